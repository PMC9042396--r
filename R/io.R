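#' Construct and validate an OTU count table
#'
#' The canonical community container used throughout the package: a
#' non-negative integer matrix with taxa as rows and samples as columns,
#' both uniquely named.
#'
#' @param counts Numeric matrix of non-negative integer counts, taxa x
#'   samples, with complete `dimnames`.
#' @return The validated matrix with class `"otu_table"` prepended.
#' @export
otu_table <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("counts must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stopf("counts must have taxon row names and sample column names")
  dup <- rownames(counts)[duplicated(rownames(counts))]
  if (length(dup)) stopf("duplicate taxon id: '%s'", dup[1])
  dup <- colnames(counts)[duplicated(colnames(counts))]
  if (length(dup)) stopf("duplicate sample id: '%s'", dup[1])
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad))
    stopf("count at [%s, %s] is not a non-negative integer",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  storage.mode(counts) <- "double"
  class(counts) <- c("otu_table", class(counts))
  counts
}

#' Read an OTU table from a tab-separated file
#'
#' @param path Path to a TSV file with one header row of identifiers and one
#'   id column.
#' @param orientation `"taxa_rows"` (default, taxa as rows) or
#'   `"samples_rows"`; either way the returned table is taxa x samples.
#' @return An [otu_table].
#' @export
read_otu_table <- function(path, orientation = c("taxa_rows", "samples_rows")) {
  orientation <- match.arg(orientation)
  # read.delim silently uniquifies duplicate column names; check the raw
  # header first
  header <- strsplit(readLines(path, n = 1), "\t", fixed = TRUE)[[1]][-1]
  dup <- header[duplicated(header)]
  if (length(dup)) stopf("duplicate identifier in '%s': '%s'", path, dup[1])
  df <- utils::read.delim(path, check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate identifier in '%s': '%s'", path, dup[1])
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- ids
  dup <- colnames(m)[duplicated(colnames(m))]
  if (length(dup)) stopf("duplicate identifier in '%s': '%s'", path, dup[1])
  if (orientation == "samples_rows") m <- t(m)
  otu_table(m)
}

#' Write an OTU table to TSV (taxa as rows)
#' @param x An [otu_table].
#' @param path Output path.
#' @export
write_otu_table <- function(x, path) {
  df <- data.frame(taxon_id = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a rooted Newick phylogeny with branch lengths
#'
#' @param path Path to a single-tree Newick file.
#' @return An [ape::read.tree] `"phylo"` object, validated to be rooted with
#'   finite non-negative branch lengths on every edge.
#' @export
read_newick <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stopf("cannot parse Newick in '%s': %s",
                                             path, conditionMessage(e)))
  if (is.null(tree)) stopf("cannot parse Newick in '%s'", path)
  validate_tree(tree)
}

#' @keywords internal
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylo object")
  if (is.null(tree$edge.length))
    stopf("tree has no branch lengths; phylogenetic dissimilarities are undefined")
  if (anyNA(tree$edge.length) || any(!is.finite(tree$edge.length)) ||
      any(tree$edge.length < 0))
    stopf("tree branch lengths must be finite and non-negative")
  if (!ape::is.rooted(tree)) stopf("tree must be rooted")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stopf("duplicate tip label: '%s'", dup[1])
  tree
}

#' Check that every taxon of a table is a tip of a tree
#' @keywords internal
check_taxa_in_tree <- function(table, tree) {
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing))
    stopf("taxon '%s' is absent from the tree", missing[1])
  invisible(TRUE)
}

STAGES <- c("A", "C", "M")

#' Construct a study design
#'
#' @param samples data.frame with columns `sample_id`, `plot_id`,
#'   `stage` (one of `"A"`, `"C"`, `"M"`).
#' @param plots data.frame with columns `plot_id`, `latitude`, `longitude`,
#'   `is_anchor` (logical). A plot's hosted stages are the stages observed
#'   among its samples; anchor plots must host all three.
#' @return A `"study_design"` list with elements `samples` and `plots` (the
#'   latter gaining a `hosted` list-column).
#' @export
study_design <- function(samples, plots) {
  need <- c("sample_id", "plot_id", "stage")
  if (!all(need %in% names(samples)))
    stopf("samples needs columns: %s", paste(need, collapse = ", "))
  need <- c("plot_id", "latitude", "longitude", "is_anchor")
  if (!all(need %in% names(plots)))
    stopf("plots needs columns: %s", paste(need, collapse = ", "))
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  plots <- as.data.frame(plots, stringsAsFactors = FALSE)
  dup <- samples$sample_id[duplicated(samples$sample_id)]
  if (length(dup)) stopf("duplicate sample id: '%s'", dup[1])
  dup <- plots$plot_id[duplicated(plots$plot_id)]
  if (length(dup)) stopf("duplicate plot id: '%s'", dup[1])
  bad <- setdiff(samples$stage, STAGES)
  if (length(bad)) stopf("unknown stage code: '%s'", bad[1])
  orphan <- setdiff(samples$plot_id, plots$plot_id)
  if (length(orphan)) stopf("sample plot '%s' is not in the plot table", orphan[1])
  if (any(abs(plots$latitude) > 90)) stopf("latitude out of [-90, 90]")
  if (any(abs(plots$longitude) > 180)) stopf("longitude out of [-180, 180]")
  hosted <- lapply(plots$plot_id, function(p)
    sort(unique(samples$stage[samples$plot_id == p])))
  names(hosted) <- plots$plot_id
  incomplete <- plots$plot_id[plots$is_anchor &
                                vapply(hosted, length, 1L) < 3L]
  if (length(incomplete))
    stopf("anchor plot '%s' does not host all three stages", incomplete[1])
  plots$hosted <- I(hosted)
  structure(list(samples = samples, plots = plots), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design: %d samples, %d plots (%d anchors)\n",
              nrow(x$samples), nrow(x$plots), sum(x$plots$is_anchor)))
  cat("Stage totals:",
      paste(sprintf("%s=%d", STAGES, vapply(
        STAGES, function(s) sum(x$samples$stage == s), 1L)), collapse = " "),
      "\n")
  invisible(x)
}

#' Read / write a study design
#'
#' The on-disk format is one flat TSV with columns `sample_id`, `plot_id`,
#' `stage`, `latitude`, `longitude`, `is_anchor` (plot attributes repeated
#' per sample).
#'
#' @param path File path.
#' @return [read_design()] returns a `"study_design"`.
#' @export
read_design <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "plot_id", "stage", "latitude", "longitude", "is_anchor")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("design file lacks column '%s'", miss[1])
  plots <- unique(df[, c("plot_id", "latitude", "longitude", "is_anchor")])
  plots$is_anchor <- as.logical(plots$is_anchor)
  study_design(df[, c("sample_id", "plot_id", "stage")], plots)
}

#' @param design A `"study_design"`.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  df <- merge(design$samples,
              design$plots[, c("plot_id", "latitude", "longitude", "is_anchor")],
              by = "plot_id", sort = FALSE)
  df <- df[order(match(df$sample_id, design$samples$sample_id)),
           c("sample_id", "plot_id", "stage", "latitude", "longitude", "is_anchor")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an environmental variable table
#'
#' Samples as rows (first column `sample_id`), variables as columns; missing
#' values permitted (`NA`).
#'
#' @param path File path.
#' @param design Optional `"study_design"`; if given, the sample set must be
#'   a subset of the design's samples.
#' @return Numeric data frame with sample ids as row names.
#' @export
read_env <- function(path, design = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup)) stopf("duplicate sample id: '%s'", dup[1])
  env <- df[, -1, drop = FALSE]
  if (!all(vapply(env, is.numeric, TRUE)))
    stopf("environmental variables must be numeric")
  rownames(env) <- ids
  if (!is.null(design)) {
    extra <- setdiff(ids, design$samples$sample_id)
    if (length(extra)) stopf("env sample '%s' is not in the design", extra[1])
  }
  env
}

#' @param env Environmental data frame (samples x variables).
#' @rdname read_env
#' @export
write_env <- function(env, path) {
  df <- data.frame(sample_id = rownames(env), env, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a distance matrix
#'
#' Accepts a `dist` or a square matrix; checks symmetry (1e-12), a zero
#' diagonal, and non-negativity; returns a labelled symmetric matrix with
#' the optional facet label attached.
#'
#' @param d `dist` object or symmetric numeric matrix with ids.
#' @param facet Optional `"taxonomic"` or `"phylogenetic"` label.
#' @return Symmetric matrix with attribute `facet`.
#' @export
as_distance_matrix <- function(d, facet = NULL) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stopf("not a square matrix")
  if (is.null(rownames(d))) stopf("distance matrix must carry ids")
  if (max(abs(d - t(d))) > 1e-12) stopf("matrix is not symmetric")
  if (any(diag(d) != 0)) stopf("diagonal must be exactly zero")
  if (any(d < 0)) stopf("distances must be non-negative")
  d <- (d + t(d)) / 2
  diag(d) <- 0
  if (!is.null(facet)) attr(d, "facet") <- match.arg(facet, c("taxonomic", "phylogenetic"))
  d
}

#' Read / write a distance matrix as TSV
#'
#' Round-trips are exact to 12 significant digits (values are written with
#' 15 significant digits).
#'
#' @param dm Distance matrix (matrix or `dist`).
#' @param path File path.
#' @export
write_distance_matrix <- function(dm, path) {
  dm <- as_distance_matrix(dm)
  df <- data.frame(id = rownames(dm),
                   format(dm, digits = 15, trim = TRUE, scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(dm))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  # symmetrise away write/parse rounding at the last digit
  as_distance_matrix((m + t(m)) / 2)
}
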