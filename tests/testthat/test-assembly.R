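test_that("betaMNTD reproduces hand values and the brute-force oracle", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  tab <- toy_otu(matrix(c(1, 0, 0, 0, 0, 1), 3, 2), taxa = c("a", "b", "c"))
  d <- bmntd(tab, tree)
  expect_equal(d["s1", "s2"], 4)
  expect_equal(d["s1", "s1"], 0)

  # identical communities: every nearest-taxon distance is conspecific
  same <- toy_otu(matrix(c(2, 1, 4, 2, 1, 4), 3, 2), taxa = c("a", "b", "c"))
  expect_equal(bmntd(same, tree)["s1", "s2"], 0)

  for (seed in 1:8) {
    set.seed(seed)
    tr <- ape::rtree(5, br = function(n) runif(n, 0.5, 2))
    tab <- random_otu(5, 4, seed = seed + 50, lambda = 2)
    rownames(tab) <- tr$tip.label
    tab <- otu_table(unclass(tab))
    for (aw in c(TRUE, FALSE))
      expect_lt(max(abs(bmntd(tab, tr, abundance_weighted = aw) -
                          brute_bmntd(tab, tr, aw))), 1e-10)
  }
})

test_that("betaMNTD agrees with picante::comdistnt", {
  skip_if_not_installed("picante")
  set.seed(3)
  tr <- ape::rcoal(12)
  tab <- random_otu(12, 6, seed = 4)
  rownames(tab) <- tr$tip.label
  tab <- otu_table(unclass(tab))
  ours <- bmntd(tab, tr)
  ref <- as.matrix(picante::comdistnt(t(unclass(tab)),
                                      ape::cophenetic.phylo(tr),
                                      abundance.weighted = TRUE))
  expect_lt(max(abs(ours - ref[rownames(ours), colnames(ours)])), 1e-10)
})

test_that("betaNTI is a z-score invariant to tip and sample order", {
  set.seed(5)
  tr <- ape::rcoal(15)
  tab <- random_otu(15, 5, seed = 6, lambda = 1)
  rownames(tab) <- tr$tip.label
  tab <- otu_table(unclass(tab))
  bn <- bnti(tab, tr, n_null = 99, seed = 7)
  expect_true(all(abs(bn$bnti[upper.tri(bn$bnti)]) < 20, na.rm = TRUE))
  expect_identical(bn$bnti, bnti(tab, tr, n_null = 99, seed = 7)$bnti)

  # reordering tree tips leaves the z-scores unchanged
  tr2 <- ape::read.tree(text = ape::write.tree(ape::rotate(
    tr, length(tr$tip.label) + 1)))
  bn2 <- bnti(tab, tr2, n_null = 99, seed = 7)
  expect_equal(bn2$bnti, bn$bnti, tolerance = 1e-10)

  # reordering samples permutes the matrix consistently
  perm <- c(4, 2, 5, 1, 3)
  bn3 <- bnti(otu_table(unclass(tab)[, perm]), tr, n_null = 99, seed = 7)
  expect_equal(bn3$bnti, bn$bnti[perm, perm], tolerance = 1e-10)
})

test_that("degenerate null distributions yield NA with a warning", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  # both samples contain all taxa: observed and null betaMNTD are all zero
  tab <- toy_otu(matrix(c(1, 1, 1, 1, 2, 2, 2, 2), 4, 2),
                 taxa = c("a", "b", "c", "d"))
  expect_warning(bn <- bnti(tab, tree, n_null = 19, seed = 1), "null SD")
  expect_true(is.na(bn$bnti["s1", "s2"]))
})

test_that("Raup-Crick stays in [-1, 1] and hits its extremes", {
  # identical paired communities from a diverse pool: obs = 0 undercuts
  # essentially every null draw
  set.seed(8)
  pool <- matrix(rpois(30 * 6, 3), 30, 6)
  pool[, 1] <- pool[, 2]   # identical pair
  tab <- toy_otu(pool)
  rc <- raup_crick_bray(tab, n_null = 199, seed = 9)
  expect_lt(rc$rc["s1", "s2"], -0.9)
  expect_true(all(rc$rc >= -1 & rc$rc <= 1))
  expect_identical(rc$rc, raup_crick_bray(tab, n_null = 199, seed = 9)$rc)
  expect_error(raup_crick_bray(toy_otu(matrix(1:2, 1, 2))), "single taxon")
})

test_that("process classification follows the threshold rules exactly", {
  ids <- c("x", "y", "z")
  mk <- function(v12, v13, v23) {
    m <- matrix(0, 3, 3, dimnames = list(ids, ids))
    m[1, 2] <- m[2, 1] <- v12
    m[1, 3] <- m[3, 1] <- v13
    m[2, 3] <- m[3, 2] <- v23
    m
  }
  b <- mk(2.5, -2.5, 0.3)
  r <- mk(0.1, 0.2, 0.2)
  cl <- classify_processes(b, r)
  expect_equal(cl$pairs$process,
               c("heterogeneous_selection", "homogeneous_selection", "drift"))

  cl2 <- classify_processes(mk(1, 0.5, -1), mk(-0.97, 0.96, 0.5))
  expect_equal(cl2$pairs$process,
               c("homogenizing_dispersal", "dispersal_limitation", "drift"))
  expect_equal(sum(cl2$proportions), 1, tolerance = 1e-12)

  # missing betaNTI excludes the pair but keeps the books balanced
  bna <- mk(NA, 3, 0)
  cl3 <- classify_processes(bna, r)
  expect_equal(cl3$n_excluded, 1)
  expect_equal(sum(cl3$proportions), 1, tolerance = 1e-12)
})

test_that("grouped proportions are reported per group", {
  set.seed(10)
  tr <- ape::rcoal(25)
  # sparse counts so communities overlap only partially and the null SD
  # stays positive for every pair
  tab <- random_otu(25, 8, seed = 11, lambda = 0.8)
  rownames(tab) <- tr$tip.label
  tab <- otu_table(unclass(tab))
  groups <- stats::setNames(rep(c("g1", "g2"), each = 4), colnames(tab))
  res <- suppressWarnings(assembly_partition(tab, tr, n_null = 49, seed = 12,
                                             groups = groups))
  expect_named(res$by_group, c("g1", "g2"))
  for (g in res$by_group) expect_equal(sum(g), 1, tolerance = 1e-12)
})
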