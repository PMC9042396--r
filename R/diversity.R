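#' Shannon diversity of one sample
#'
#' `H = -sum p_i log p_i` over taxa with positive counts, in nats by
#' default.
#'
#' @param counts Non-negative abundance vector with at least one positive
#'   entry.
#' @param base Logarithm base (default `exp(1)`; use 2 for bits).
#' @return Shannon index (scalar).
#' @export
shannon <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stopf("counts must be non-negative")
  if (sum(counts) <= 0) stopf("all-zero abundance vector")
  as.numeric(vegan::diversity(counts, index = "shannon", base = base))
}

#' @keywords internal
check_positive_samples <- function(table) {
  empty <- colnames(table)[colSums(table) <= 0]
  if (length(empty)) stopf("sample '%s' has zero total count", empty[1])
  invisible(TRUE)
}

#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, computed on per-sample
#' relative abundances by default (raw counts available for count-level
#' analyses); values lie in `[0, 1]`.
#'
#' @param table An [otu_table] (taxa x samples).
#' @param transform `"relative"` (default) or `"raw"`.
#' @return Symmetric distance matrix (samples x samples) with
#'   `attr(, "facet") == "taxonomic"`.
#' @export
bray_curtis <- function(table, transform = c("relative", "raw")) {
  transform <- match.arg(transform)
  check_positive_samples(table)
  m <- t(unclass(table))
  if (transform == "relative") m <- m / rowSums(m)
  as_distance_matrix(vegan::vegdist(m, method = "bray"), facet = "taxonomic")
}

#' @keywords internal
relative_abundance <- function(table) {
  m <- unclass(table)
  sweep(m, 2, colSums(m), "/")
}

#' Per-branch descendant abundance fractions
#'
#' For every edge of the tree, the fraction of each sample's individuals
#' carried by tips descending from that edge. Rows are edges (in
#' `tree$edge` order), columns samples.
#' @keywords internal
branch_fractions <- function(table, tree) {
  check_taxa_in_tree(table, tree)
  tree <- ape::keep.tip(tree, rownames(table))
  p <- relative_abundance(table)[tree$tip.label, , drop = FALSE]
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  acc <- matrix(0, n_node, ncol(p))
  acc[seq_len(n_tip), ] <- p
  # postorder: children are accumulated before their parent edge is read
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]
    child <- ord$edge[e, 2]
    acc[parent, ] <- acc[parent, ] + acc[child, ]
  }
  A <- acc[ord$edge[, 2], , drop = FALSE]
  colnames(A) <- colnames(p)
  list(A = A, lengths = ord$edge.length, tree = ord)
}

#' Weighted UniFrac dissimilarity
#'
#' Phylogenetic dissimilarity between samples:
#' `raw WU(x, y) = sum_b l_b |A_bx - A_by|`, where `A_bx` is the fraction
#' of sample x's individuals descending from branch b. When
#' `normalized = TRUE` (default) the raw value is divided by
#' `sum_b l_b (A_bx + A_by)`, bounding it in `[0, 1]`.
#'
#' @param table An [otu_table]; every taxon must be a tree tip.
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param normalized Divide by the pairwise maximum attainable value?
#' @return Symmetric distance matrix with `attr(, "facet") ==
#'   "phylogenetic"`.
#' @export
weighted_unifrac <- function(table, tree, normalized = TRUE) {
  check_positive_samples(table)
  bf <- branch_fractions(table, tree)
  W <- bf$A * bf$lengths
  raw <- as.matrix(stats::dist(t(W), method = "manhattan"))
  if (normalized) {
    s <- colSums(W)
    denom <- outer(s, s, "+")
    d <- raw / ifelse(denom > 0, denom, 1)
  } else {
    d <- raw
  }
  as_distance_matrix(d, facet = "phylogenetic")
}
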