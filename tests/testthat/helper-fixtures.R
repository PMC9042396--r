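# Small fixtures and independent brute-force oracles used across the suite.

toy_otu <- function(counts, taxa = NULL, samples = NULL) {
  if (is.null(taxa)) taxa <- paste0("t", seq_len(nrow(counts)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(counts)))
  dimnames(counts) <- list(taxa, samples)
  otu_table(counts)
}

random_otu <- function(n_taxa, n_samples, seed, lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples)
  m[, colSums(m) == 0] <- 1
  toy_otu(m)
}

# brute-force weighted UniFrac: enumerate every branch, collect its
# descendant tips independently of the package's postorder accumulation
brute_unifrac <- function(table, tree, normalized = TRUE) {
  tree <- ape::keep.tip(tree, rownames(table))
  p <- sweep(unclass(table), 2, colSums(table), "/")[tree$tip.label, ,
                                                     drop = FALSE]
  n_tip <- length(tree$tip.label)
  tips_under <- function(node) {
    if (node <= n_tip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  n <- ncol(p)
  raw <- den <- matrix(0, n, n, dimnames = list(colnames(p), colnames(p)))
  for (e in seq_len(nrow(tree$edge))) {
    tips <- tips_under(tree$edge[e, 2])
    a <- colSums(p[tips, , drop = FALSE])
    l <- tree$edge.length[e]
    raw <- raw + l * abs(outer(a, a, "-"))
    den <- den + l * outer(a, a, "+")
  }
  if (normalized) raw / ifelse(den > 0, den, 1) else raw
}

# brute-force betaMNTD: explicit double loop over taxon pairs
brute_bmntd <- function(table, tree, abundance_weighted = TRUE) {
  coph <- ape::cophenetic.phylo(ape::keep.tip(tree, rownames(table)))
  m <- unclass(table)
  n <- ncol(m)
  out <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ta <- rownames(m)[m[, i] > 0]
    tb <- rownames(m)[m[, j] > 0]
    fa <- if (abundance_weighted) m[ta, i] / sum(m[, i]) else
      rep(1 / length(ta), length(ta))
    s <- 0
    for (k in seq_along(ta)) s <- s + fa[k] * min(coph[ta[k], tb])
    out[i, j] <- s
  }
  (out + t(out)) / 2
}

# classical within/between sum-of-squares PERMANOVA for a categorical
# predictor (Anderson 2001), independent of the Gower/hat-matrix route
brute_permanova_r2 <- function(dm, groups) {
  d2 <- dm^2
  n <- nrow(dm)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  (ss_total - ss_within) / ss_total
}

brute_permanova_f <- function(dm, groups) {
  r2 <- brute_permanova_r2(dm, groups)
  a <- length(unique(groups))
  n <- nrow(dm)
  (r2 / (a - 1)) / ((1 - r2) / (n - a))
}

# all-pairs BFS shortest paths and direct edge counting for network
# summaries; adjacency in, metrics out
brute_topology <- function(adj) {
  n <- nrow(adj)
  e <- sum(adj[upper.tri(adj)] != 0)
  dists <- c()
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] != 0)) if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
    dists <- c(dists, dist[seq_len(n) > s & is.finite(dist)])
  }
  list(n_nodes = n, n_edges = e, edges_per_node = e / n,
       average_degree = 2 * e / n, average_path_distance = mean(dists))
}

# independent constrained-combination enumerator working from the raw
# sample table (checks both constraints explicitly, no hosted shortcut)
brute_combinations <- function(design, k) {
  ids <- sort(design$plots$plot_id)
  anchors <- design$plots$plot_id[design$plots$is_anchor]
  combos <- utils::combn(ids, k, simplify = FALSE)
  Filter(function(cmb) {
    samp <- design$samples[design$samples$plot_id %in% cmb, ]
    length(intersect(cmb, anchors)) >= 1 &&
      setequal(unique(samp$stage), c("A", "C", "M"))
  }, combos)
}
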