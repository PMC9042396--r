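fake_corr <- function(r) {
  diag(r) <- 1
  list(r = r, p = matrix(0, nrow(r), ncol(r),
                         dimnames = dimnames(r)), n_samples = 10,
       method = "spearman")
}

named_mat <- function(n, prefix = "t") {
  matrix(0, n, n, dimnames = list(paste0(prefix, 1:n), paste0(prefix, 1:n)))
}

test_that("correlation matrices flag perfect and degenerate profiles", {
  # equal sample totals so per-sample normalisation preserves the patterns
  base <- rbind(t1 = c(1, 2, 3, 4),
                t2 = c(2, 4, 6, 8),    # duplicated profile, scaled
                t3 = c(9, 8, 7, 6),    # reversed pattern
                t4 = c(8, 6, 4, 2))
  colnames(base) <- paste0("s", 1:4)
  tab <- otu_table(base)
  cm <- correlation_matrix(tab, method = "spearman", min_prevalence = 0)
  expect_equal(cm$r["t1", "t2"], 1)
  expect_equal(cm$r["t1", "t3"], -1)

  # constant relative-abundance profile is excluded with a warning:
  # equalise sample totals and hold one row fixed
  cmat <- matrix(c(4, 2, 2,
                   4, 3, 1,
                   4, 1, 3,
                   4, 2, 2), 3, 4,
                 dimnames = list(paste0("t", 1:3), paste0("s", 1:4)))
  expect_warning(cm2 <- correlation_matrix(otu_table(cmat),
                                           min_prevalence = 0),
                 "constant")
  expect_false("t1" %in% rownames(cm2$r))

  expect_error(correlation_matrix(otu_table(base[, 1:3]),
                                  min_prevalence = 0), "4 samples")
})

test_that("network construction thresholds edges and recovers modules", {
  r <- named_mat(6)
  r[1:3, 1:3] <- 0.95
  r[4:6, 4:6] <- 0.95
  r[3, 4] <- r[4, 3] <- 0.85
  net <- build_network(fake_corr(r), r_threshold = 0.8)
  expect_equal(igraph::gsize(net$graph), 7)
  # the two planted cliques come back as the two modules
  memb <- split(names(net$membership), net$membership)
  expect_true(setequal(memb[[1]], paste0("t", 1:3)) ||
                setequal(memb[[1]], paste0("t", 4:6)))
  expect_equal(length(memb), 2)

  # all-positive complete graph: coexistence is 100%
  rall <- named_mat(4)
  rall[] <- 0.9
  summ <- topology_summary(build_network(fake_corr(rall)))
  expect_equal(summ$coexistence_pct, 100)
  expect_equal(summ$mutual_exclusion_pct, 0)

  expect_error(build_network(fake_corr(named_mat(4)), r_threshold = 0.99),
               "threshold")
})

test_that("topology summaries match hand values and brute-force BFS", {
  # path graph a-b-c: mean shortest path = (1 + 1 + 2) / 3
  r <- named_mat(3, "n")
  r[1, 2] <- r[2, 1] <- 0.9
  r[2, 3] <- r[3, 2] <- 0.9
  s <- topology_summary(build_network(fake_corr(r)))
  expect_equal(s$average_path_distance, 4 / 3, tolerance = 1e-12)

  # complete graph: every pair at distance 1
  rc <- named_mat(5)
  rc[] <- 0.85
  sc <- topology_summary(build_network(fake_corr(rc)))
  expect_equal(sc$average_path_distance, 1)
  expect_equal(sc$edges_per_node, 2)
  expect_equal(sc$average_degree, 4)

  # random graphs against the BFS/counting oracle
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(8:14, 1)
    adj <- matrix(0, n, n)
    idx <- which(upper.tri(adj))
    on <- sample(idx, max(n, round(length(idx) * 0.3)))
    adj[on] <- 1
    adj <- adj + t(adj)
    adj <- adj[rowSums(adj) > 0, rowSums(adj) > 0]
    dimnames(adj) <- list(paste0("v", seq_len(nrow(adj))),
                          paste0("v", seq_len(nrow(adj))))
    net <- build_network(fake_corr(adj * 0.9))
    got <- topology_summary(net)
    want <- brute_topology(adj)
    for (f in names(want))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12, label = f)
    expect_equal(got$coexistence_pct + got$mutual_exclusion_pct, 100,
                 tolerance = 1e-9)
  }
})

test_that("Zi-Pi reproduces hand examples and classifies key taxa", {
  # module with within-degrees {3,1,1,1} plus a separate module: the hub
  # has z = (3 - 1.5) / sqrt(3/4)
  r <- named_mat(7, "n")
  r[1, 2:4] <- r[cbind(2:4, 1)] <- 0.9
  r[5, 6] <- r[6, 5] <- 0.9
  r[6, 7] <- r[7, 6] <- 0.9
  net <- build_network(fake_corr(r))
  roles <- zi_pi(net)
  expect_equal(roles$roles$zi[roles$roles$node == "n1"], sqrt(3),
               tolerance = 1e-10)
  expect_equal(roles$roles$pi, rep(0, 7))
  expect_equal(roles$key_pct + roles$peripheral_pct, 100, tolerance = 1e-9)

  # degree-4 node split 2/2 across two modules: Pi = 1 - 2 * 0.25
  r2 <- named_mat(9, "m")
  r2[1:4, 1:4] <- 0.9   # clique A
  r2[5:8, 5:8] <- 0.9   # clique B
  r2[9, c(1, 2, 5, 6)] <- r2[c(1, 2, 5, 6), 9] <- 0.9
  net2 <- build_network(fake_corr(r2))
  memb <- net2$membership
  # force the bridge node into its own evaluation context: its four edges
  # split 2/2 whichever clique it joins
  roles2 <- zi_pi(net2, pi_threshold = 0.45)
  bridge <- roles2$roles[roles2$roles$node == "m9", ]
  expect_equal(bridge$pi, 0.5, tolerance = 1e-10)
  expect_true(bridge$is_key)
  expect_equal(bridge$category, "connector")

  # Zi is invariant to adding an isolated module elsewhere
  r3 <- named_mat(10, "n")
  r3[1:7, 1:7] <- r[1:7, 1:7]
  r3[8, 9] <- r3[9, 8] <- 0.9
  r3[9, 10] <- r3[10, 9] <- 0.9
  net3 <- build_network(fake_corr(r3))
  roles3 <- zi_pi(net3)
  expect_equal(roles3$roles$zi[roles3$roles$node == "n1"], sqrt(3),
               tolerance = 1e-10)
})

test_that("the RMT scan prefers thresholds that decouple planted blocks", {
  set.seed(14)
  # two independent latent factors drive two OTU blocks; cross-block
  # correlations are noise
  n_s <- 40
  f1 <- rnorm(n_s); f2 <- rnorm(n_s)
  x <- rbind(t(sapply(1:12, function(i) f1 * 2 + rnorm(n_s, 0, 0.6))),
             t(sapply(1:12, function(i) f2 * 2 + rnorm(n_s, 0, 0.6))))
  rownames(x) <- paste0("o", 1:24)
  cm <- list(r = cor(t(x)), p = matrix(0, 24, 24,
                                       dimnames = list(rownames(x),
                                                       rownames(x))))
  sc <- rmt_threshold_scan(cm, grid = seq(0.3, 0.9, 0.05))
  expect_true(is.na(sc$threshold) || sc$threshold <= 0.9)
  if (!is.na(sc$threshold)) {
    planted <- (outer(1:24, 1:24, function(i, j)
      (i <= 12) == (j <= 12)))
    picked <- abs(cm$r) >= sc$threshold
    diag(picked) <- FALSE
    # precision on planted within-block edges
    expect_gte(sum(picked & planted) / sum(picked), 0.9)
  }
  # degenerate one-point grid returns that threshold or none
  sc1 <- rmt_threshold_scan(cm, grid = 0.5)
  expect_true(is.na(sc1$threshold) || sc1$threshold == 0.5)
  expect_error(rmt_threshold_scan(cm, grid = c(0.5, 0.3)), "ascending")
})
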