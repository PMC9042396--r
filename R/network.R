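#' Pairwise OTU correlations with p-values
#'
#' Correlates OTU abundance profiles (per-sample relative abundances)
#' across samples, after a prevalence filter. Two-sided p-values use the
#' t approximation `t = r sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom (applied to the rank correlation for Spearman). Constant OTU
#' profiles are excluded with a warning.
#'
#' @param table An [otu_table] with >= 4 samples.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_prevalence Minimum fraction of samples in which an OTU must
#'   occur (default 0.2).
#' @return List with matrices `r` and `p` over the retained OTUs, plus
#'   `n_samples` and `method`.
#' @export
correlation_matrix <- function(table, method = c("spearman", "pearson"),
                               min_prevalence = 0.2) {
  method <- match.arg(method)
  m <- unclass(table)
  if (ncol(m) < 4) stopf("need at least 4 samples")
  keep <- rowMeans(m > 0) >= min_prevalence
  m <- m[keep, , drop = FALSE]
  rel <- sweep(m, 2, pmax(colSums(m), 1), "/")
  const <- apply(rel, 1, function(x) stats::var(x) == 0)
  if (any(const)) {
    warnf("excluding %d constant OTU profile(s)", sum(const))
    rel <- rel[!const, , drop = FALSE]
  }
  if (nrow(rel) < 2) stopf("fewer than 2 OTUs pass the filters")
  n <- ncol(rel)
  x <- if (method == "spearman") t(apply(rel, 1, rank)) else rel
  r <- stats::cor(t(x))
  r_clip <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tval <- r_clip * sqrt((n - 2) / (1 - r_clip^2))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  diag(p) <- 0
  list(r = r, p = p, n_samples = n, method = method)
}

#' Build a signed co-occurrence network
#'
#' Draws an undirected edge between two OTUs when `|r| >= r_threshold` and
#' `p <= p_max`; edge sign is the correlation sign (`+` coexistence, `-`
#' mutual exclusion). Isolated nodes are dropped. Modules are found by
#' greedy modularity maximization on `|r|` edge weights.
#'
#' @param corr Result of [correlation_matrix()] (or a list with `r`, `p`).
#' @param r_threshold Absolute-correlation cutoff (default 0.8).
#' @param p_max Maximum p-value (default 0.05).
#' @return A `"cooccurrence_network"` list: `graph` (igraph, with `sign`
#'   and `weight` edge attributes), `membership` (module id per node),
#'   `edges` (data frame: `node_1`, `node_2`, `sign`, `weight`).
#' @export
build_network <- function(corr, r_threshold = 0.8, p_max = 0.05) {
  r <- corr$r
  p <- corr$p
  adj <- abs(r) >= r_threshold & p <= p_max
  diag(adj) <- FALSE
  if (!any(adj))
    stopf("no edges at |r| >= %g, p <= %g; lower the threshold", r_threshold, p_max)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  g <- igraph::delete_vertices(g, igraph::degree(g) == 0)
  ends <- igraph::as_edgelist(g)
  w <- r[cbind(match(ends[, 1], rownames(r)), match(ends[, 2], rownames(r)))]
  igraph::E(g)$weight <- w
  igraph::E(g)$sign <- ifelse(w >= 0, "+", "-")
  comm <- igraph::cluster_fast_greedy(g, weights = abs(w))
  membership <- igraph::membership(comm)
  structure(list(graph = g, membership = membership,
                 edges = data.frame(node_1 = ends[, 1], node_2 = ends[, 2],
                                    sign = igraph::E(g)$sign, weight = w,
                                    stringsAsFactors = FALSE)),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("Co-occurrence network: %d nodes, %d edges, %d modules\n",
              igraph::gorder(x$graph), igraph::gsize(x$graph),
              length(unique(x$membership))))
  invisible(x)
}

#' Random-matrix-theory threshold scan
#'
#' Approximates the RMT criterion used by molecular-ecological-network
#' pipelines: for each candidate threshold the correlation matrix is
#' hard-thresholded (entries with `|r| <` threshold zeroed), its
#' eigenvalues are unfolded with a smoothing spline of the empirical
#' spectral CDF, and the nearest-neighbour spacing distribution is tested
#' against the Poisson (exponential) form by a chi-squared
#' goodness-of-fit test. The suggested threshold is the smallest one whose
#' spacings are not rejected at `alpha`; modular signal decouples the
#' spectrum (Poisson spacings) while noise keeps Wigner-like repulsion.
#'
#' @param corr Result of [correlation_matrix()].
#' @param grid Ascending candidate thresholds.
#' @param alpha Rejection level (default 0.05).
#' @param n_bins Chi-squared histogram bins (default 10).
#' @return List with `threshold` (or `NA` if none qualifies) and `scan`
#'   (data frame of threshold, chi-squared p-value, edge count).
#' @export
rmt_threshold_scan <- function(corr, grid, alpha = 0.05, n_bins = 10) {
  if (is.unsorted(grid)) stopf("grid must be ascending")
  r <- corr$r
  scan <- lapply(grid, function(th) {
    b <- r
    b[abs(b) < th] <- 0
    diag(b) <- 1
    ev <- sort(eigen(b, symmetric = TRUE, only.values = TRUE)$values)
    ev <- unique(round(ev, 10))
    n <- length(ev)
    if (n < n_bins + 2)
      return(data.frame(threshold = th, p_value = NA_real_,
                        n_edges = sum(abs(r) >= th & upper.tri(r))))
    # unfold: map eigenvalues through a smoothed empirical CDF so spacings
    # have unit mean
    cdf <- stats::smooth.spline(ev, seq_len(n) / n, spar = 0.7)
    u <- stats::predict(cdf, ev)$y * n
    s <- diff(u)
    s <- s[s > 0]
    s <- s / mean(s)
    # chi-squared GOF against Exp(1) spacings (Poisson statistics)
    brks <- c(stats::qexp(seq(0, 1, length.out = n_bins + 1)[-(n_bins + 1)]), Inf)
    obs <- table(cut(s, brks, include.lowest = TRUE))
    expd <- length(s) / n_bins
    chi2 <- sum((as.numeric(obs) - expd)^2 / expd)
    pv <- stats::pchisq(chi2, df = n_bins - 1, lower.tail = FALSE)
    data.frame(threshold = th, p_value = pv,
               n_edges = sum(abs(r) >= th & upper.tri(r)))
  })
  scan <- do.call(rbind, scan)
  ok <- which(!is.na(scan$p_value) & scan$p_value >= alpha)
  list(threshold = if (length(ok)) scan$threshold[ok[1]] else NA_real_,
       scan = scan)
}

#' Topology summary of a co-occurrence network
#'
#' The standard table of network features: node and edge counts, percent
#' positive (coexistence) and negative (mutual exclusion) edges, edges per
#' node, average degree (`2E/N`), average shortest-path distance over
#' connected node pairs, and the modularity of the module partition.
#'
#' @param net A `"cooccurrence_network"`.
#' @return A `"network_summary"` list of the above fields.
#' @export
topology_summary <- function(net) {
  g <- net$graph
  n <- igraph::gorder(g)
  e <- igraph::gsize(g)
  if (e < 1) stopf("network has no edges")
  pos <- sum(igraph::E(g)$sign == "+")
  structure(list(
    n_nodes = n, n_edges = e,
    coexistence_pct = 100 * pos / e,
    mutual_exclusion_pct = 100 * (e - pos) / e,
    edges_per_node = e / n,
    average_degree = 2 * e / n,
    average_path_distance = igraph::mean_distance(g, directed = FALSE,
                                                  unconnected = TRUE,
                                                  weights = NA),
    modularity = igraph::modularity(g, net$membership,
                                    weights = rep(1, e))),
    class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf(paste0("Nodes %d | Edges %d | Coexistence %.3f%% | ",
                     "Mutual exclusion %.3f%%\nEdges/node %.3f | ",
                     "Avg degree %.3f | Avg path %.3f | Modularity %.3f\n"),
              x$n_nodes, x$n_edges, x$coexistence_pct,
              x$mutual_exclusion_pct, x$edges_per_node, x$average_degree,
              x$average_path_distance, x$modularity))
  invisible(x)
}

#' Zi-Pi node-role classification
#'
#' Within-module degree z-score
#' `Zi = (k_i,own - mean(k_own)) / sd_pop(k_own)` (population SD over the
#' node's module; 0 when the module SD is 0) and among-module participation
#' coefficient `Pi = 1 - sum_m (k_i,m / k_i)^2`. Roles: peripheral
#' (`Zi < zi_threshold`, `Pi < pi_threshold`), connector (low Zi, high Pi),
#' module hub (high Zi, low Pi), network hub (both high). Key taxa are all
#' non-peripheral nodes.
#'
#' @param net A `"cooccurrence_network"`.
#' @param zi_threshold Hub cutoff on Zi (default 2.5).
#' @param pi_threshold Connector cutoff on Pi (default 0.62).
#' @return A `"node_roles"` list: `roles` (data frame with `node`, `zi`,
#'   `pi`, `category`, `is_key`), `key_pct`, `peripheral_pct`.
#' @export
zi_pi <- function(net, zi_threshold = 2.5, pi_threshold = 0.62) {
  g <- net$graph
  memb <- net$membership
  nodes <- igraph::V(g)$name
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  k <- rowSums(adj)
  mods <- sort(unique(memb))
  # k_im: edges from node i into module m
  k_im <- vapply(mods, function(m) rowSums(adj[, memb == m, drop = FALSE]),
                 numeric(length(nodes)))
  k_own <- k_im[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (m in mods) {
    idx <- memb == m
    mu <- mean(k_own[idx])
    sd_pop <- sqrt(mean((k_own[idx] - mu)^2))
    zi[idx] <- if (sd_pop == 0) 0 else (k_own[idx] - mu) / sd_pop
  }
  pi_val <- 1 - rowSums((k_im / k)^2)
  category <- ifelse(zi >= zi_threshold & pi_val >= pi_threshold, "network_hub",
              ifelse(zi >= zi_threshold, "module_hub",
              ifelse(pi_val >= pi_threshold, "connector", "peripheral")))
  roles <- data.frame(node = nodes, zi = zi, pi = pi_val,
                      category = category,
                      is_key = category != "peripheral",
                      stringsAsFactors = FALSE)
  structure(list(roles = roles,
                 key_pct = 100 * mean(roles$is_key),
                 peripheral_pct = 100 * mean(!roles$is_key),
                 zi_threshold = zi_threshold, pi_threshold = pi_threshold),
            class = "node_roles")
}

#' @export
print.node_roles <- function(x, ...) {
  cat(sprintf("Node roles: %.2f%% key, %.2f%% peripheral (Zi >= %.2f, Pi >= %.2f)\n",
              x$key_pct, x$peripheral_pct, x$zi_threshold, x$pi_threshold))
  print(table(x$roles$category))
  invisible(x)
}
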