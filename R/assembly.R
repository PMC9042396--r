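#' Between-community mean nearest-taxon distance (betaMNTD)
#'
#' For a pair of communities A and B,
#' `betaMNTD = 1/2 * (sum_i f_iA min_j d(i, j) + sum_j f_jB min_i d(i, j))`
#' with `i` over taxa of A, `j` over taxa of B, `f` relative abundances
#' (or `1/richness` when unweighted), and `d` the cophenetic distance on
#' the tree. A taxon present in both communities contributes 0 (its nearest
#' taxon is its conspecific).
#'
#' @param table An [otu_table]; taxa must be tree tips.
#' @param tree Rooted `"phylo"` with branch lengths.
#' @param abundance_weighted Weight by relative abundances (default) or
#'   equally across present taxa.
#' @param coph Optional precomputed cophenetic matrix over the table's taxa
#'   (used internally by the null loop).
#' @return Symmetric distance matrix (samples x samples).
#' @export
bmntd <- function(table, tree = NULL, abundance_weighted = TRUE, coph = NULL) {
  check_positive_samples(table)
  if (is.null(coph)) {
    check_taxa_in_tree(table, tree)
    tree <- ape::keep.tip(tree, rownames(table))
    coph <- ape::cophenetic.phylo(tree)
  }
  taxa <- rownames(table)
  coph <- coph[taxa, taxa]
  f <- if (abundance_weighted) relative_abundance(table) else {
    pres <- unclass(table) > 0
    sweep(pres * 1, 2, colSums(pres), "/")
  }
  pres <- unclass(table) > 0
  # m[, s]: for each taxon, distance to its nearest taxon present in sample s
  m <- vapply(seq_len(ncol(table)), function(s) {
    d <- coph[, pres[, s], drop = FALSE]
    apply(d, 1, min)
  }, numeric(nrow(table)))
  half <- crossprod(f, m)   # half[a, b] = sum_i f_ia * m_ib
  d <- (half + t(half)) / 2
  dimnames(d) <- list(colnames(table), colnames(table))
  diag(d) <- 0
  as_distance_matrix(d)
}

#' beta nearest-taxon index (betaNTI)
#'
#' Z-score of the observed betaMNTD against a null distribution obtained by
#' shuffling taxon labels across all tree tips (one global shuffle per
#' replicate, preserving tree shape and community abundances) and
#' recomputing betaMNTD. `|betaNTI| > 2` signals deterministic selection:
#' `> 2` heterogeneous (communities more phylogenetically divergent than
#' expected), `< -2` homogeneous.
#'
#' @param table An [otu_table].
#' @param tree Rooted `"phylo"`; tips may exceed the table's taxa.
#' @param n_null Null replicates (default 999).
#' @param seed Integer seed.
#' @param abundance_weighted Passed to [bmntd()].
#' @return List with `bnti` (z-score matrix; `NA` with a warning where the
#'   null SD is 0), `bmntd_obs`, `n_null`, `seed`.
#' @export
bnti <- function(table, tree, n_null = 999, seed = 1,
                 abundance_weighted = TRUE) {
  check_taxa_in_tree(table, tree)
  tree <- ape::keep.tip(tree, rownames(table))
  taxa <- rownames(table)
  # canonical taxon order so the seeded null is invariant to tip order
  coph <- ape::cophenetic.phylo(tree)[taxa, taxa]
  obs <- bmntd(table, coph = coph, abundance_weighted = abundance_weighted)
  n <- ncol(table)
  sum1 <- matrix(0, n, n)
  sum2 <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(n_null)) {
      shuf <- sample(taxa)
      cp <- coph
      dimnames(cp) <- list(shuf, shuf)
      d <- bmntd(table, coph = cp, abundance_weighted = abundance_weighted)
      sum1 <- sum1 + d
      sum2 <- sum2 + d^2
    }
  })
  mu <- sum1 / n_null
  # pmax's result takes the first argument's attributes: keep the matrix
  sdv <- sqrt(pmax(sum2 / n_null - mu^2, 0))
  z <- (obs - mu) / sdv
  degenerate <- sdv == 0 & upper.tri(sdv)
  if (any(degenerate)) {
    warnf("null SD is zero for %d sample pair(s); betaNTI set to NA",
          sum(degenerate))
  }
  z[sdv == 0] <- NA
  diag(z) <- 0
  list(bnti = z, bmntd_obs = obs, n_null = n_null, seed = seed)
}

#' Raup-Crick index on Bray-Curtis dissimilarities (RC_bray)
#'
#' For each sample pair, the observed Bray-Curtis dissimilarity (raw
#' counts) is ranked within a null distribution of dissimilarities between
#' randomly assembled communities: each null community keeps its sample's
#' observed richness and total abundance, draws which taxa occur with
#' probability proportional to regional occupancy (one individual each),
#' receives one individual per drawn taxon, and fills the remaining
#' individuals with probability proportional to regional relative abundance
#' among the drawn taxa (richness and total abundance are thus preserved
#' exactly).
#' `RC = 2 * (P(null < obs) + 0.5 * P(null = obs)) - 1`, in `[-1, 1]`:
#' below -0.95 communities are more similar than random assembly predicts
#' (homogenizing dispersal), above +0.95 more different (dispersal
#' limitation).
#'
#' @param table An [otu_table] with >= 2 samples and >= 2 taxa.
#' @param n_null Null replicates (default 999).
#' @param seed Integer seed.
#' @return List with `rc` (matrix in `[-1, 1]`), `n_null`, `seed`.
#' @export
raup_crick_bray <- function(table, n_null = 999, seed = 1) {
  check_positive_samples(table)
  m <- unclass(table)
  if (nrow(m) < 2) stopf("regional pool has a single taxon")
  n_taxa <- nrow(m)
  n_samp <- ncol(m)
  occupancy <- rowSums(m > 0)
  regional <- rowSums(m)
  richness <- colSums(m > 0)
  totals <- colSums(m)

  assemble <- function(R, N) {
    idx <- sample.int(n_taxa, R, prob = occupancy)
    x <- numeric(n_taxa)
    x[idx] <- 1
    if (N > R)
      x[idx] <- x[idx] + stats::rmultinom(1, N - R, regional[idx])[, 1]
    x
  }
  bc <- function(x, y) sum(abs(x - y)) / sum(x + y)

  with_seed(seed, {
    # one stack of null realizations per sample; replicate r pairs
    # null_i[r] with null_j[r]
    nulls <- lapply(seq_len(n_samp), function(s)
      vapply(seq_len(n_null), function(r) assemble(richness[s], totals[s]),
             numeric(n_taxa)))
    rc <- matrix(0, n_samp, n_samp,
                 dimnames = list(colnames(m), colnames(m)))
    for (i in seq_len(n_samp - 1)) for (j in (i + 1):n_samp) {
      obs <- bc(m[, i], m[, j])
      null_d <- colSums(abs(nulls[[i]] - nulls[[j]])) /
        colSums(nulls[[i]] + nulls[[j]])
      below <- sum(null_d < obs - 1e-12)
      ties <- sum(abs(null_d - obs) <= 1e-12)
      rc[i, j] <- rc[j, i] <- 2 * ((below + 0.5 * ties) / n_null) - 1
    }
  })
  list(rc = rc, n_null = n_null, seed = seed)
}

PROCESSES <- c("heterogeneous_selection", "homogeneous_selection",
               "homogenizing_dispersal", "dispersal_limitation", "drift")

#' Classify assembly processes from betaNTI and RC_bray
#'
#' Per sample pair: `betaNTI > 2` heterogeneous selection; `betaNTI < -2`
#' homogeneous selection; otherwise `RC < -0.95` homogenizing dispersal,
#' `RC > +0.95` dispersal limitation, and drift in between. Pairs with a
#' missing betaNTI are excluded (their count is reported).
#'
#' @param bnti_dm betaNTI z-score matrix (from [bnti()]).
#' @param rc_dm RC_bray matrix (from [raup_crick_bray()]), same samples.
#' @param groups Optional per-sample labels; proportions are then also
#'   reported per group (both members in the group) in `by_group`.
#' @return An `"assembly_classification"` list: `pairs` (data frame with
#'   `sample_1`, `sample_2`, `bnti`, `rc`, `process`), `proportions`
#'   (summing to 1 over classified pairs), `n_excluded`, optionally
#'   `by_group`.
#' @export
classify_processes <- function(bnti_dm, rc_dm, groups = NULL) {
  if (!identical(rownames(bnti_dm), rownames(rc_dm)))
    stopf("betaNTI and RC matrices cover different samples")
  n <- nrow(bnti_dm)
  ut <- which(upper.tri(bnti_dm), arr.ind = TRUE)
  b <- bnti_dm[ut]
  r <- rc_dm[ut]
  process <- ifelse(b > 2, "heterogeneous_selection",
             ifelse(b < -2, "homogeneous_selection",
             ifelse(r < -0.95, "homogenizing_dispersal",
             ifelse(r > 0.95, "dispersal_limitation", "drift"))))
  pairs <- data.frame(sample_1 = rownames(bnti_dm)[ut[, 1]],
                      sample_2 = rownames(bnti_dm)[ut[, 2]],
                      bnti = b, rc = r, process = process,
                      stringsAsFactors = FALSE)
  excluded <- is.na(pairs$process)
  prop <- function(p) {
    tab <- table(factor(p, levels = PROCESSES))
    stats::setNames(as.numeric(tab) / length(p), PROCESSES)
  }
  out <- list(pairs = pairs,
              proportions = prop(pairs$process[!excluded]),
              n_excluded = sum(excluded))
  if (!is.null(groups)) {
    groups <- align_predictor(groups, rownames(bnti_dm))
    g1 <- groups[match(pairs$sample_1, rownames(bnti_dm))]
    g2 <- groups[match(pairs$sample_2, rownames(bnti_dm))]
    keep <- !excluded & g1 == g2
    out$by_group <- lapply(split(pairs$process[keep], g1[keep]), prop)
  }
  structure(out, class = "assembly_classification")
}

#' @export
print.assembly_classification <- function(x, ...) {
  cat(sprintf("Assembly classification over %d pairs (%d excluded)\n",
              nrow(x$pairs), x$n_excluded))
  print(round(x$proportions, 3))
  invisible(x)
}

#' Full assembly partitioning of a dataset
#'
#' Convenience wrapper running [bnti()], [raup_crick_bray()], and
#' [classify_processes()].
#'
#' @inheritParams bnti
#' @inheritParams classify_processes
#' @param n_null Null replicates for both null models.
#' @return An `"assembly_classification"` with the two input matrices
#'   attached as `bnti_dm` and `rc_dm`.
#' @export
assembly_partition <- function(table, tree, n_null = 999, seed = 1,
                               groups = NULL) {
  bn <- bnti(table, tree, n_null = n_null, seed = stage_seed(seed, 1))
  rc <- raup_crick_bray(table, n_null = n_null, seed = stage_seed(seed, 2))
  out <- classify_processes(bn$bnti, rc$rc, groups = groups)
  out$bnti_dm <- bn$bnti
  out$rc_dm <- rc$rc
  out
}
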