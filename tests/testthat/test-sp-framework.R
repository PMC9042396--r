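test_that("constrained enumeration matches the combinatorial identity", {
  d <- make_study_design()
  for (k in c(3, 6, 10)) {
    combos <- enumerate_combinations(d, k)
    expect_equal(length(combos), choose(13, k) - choose(9, k))
    # independent double-constraint enumerator agrees subset by subset
    expect_identical(combos, brute_combinations(d, k))
  }
  # a subset without an anchor is rejected
  combos3 <- enumerate_combinations(d, 3)
  expect_false(any(vapply(combos3, setequal, TRUE,
                          y = c("JC", "BQ", "LQ"))))
  expect_error(enumerate_combinations(d, 2), "k must be")
})

test_that("combination geographic extent is the farthest-pair haversine", {
  d <- make_study_design()
  plots <- d$plots
  # coincident plots
  same <- plots
  same$latitude <- 40
  same$longitude <- 100
  d2 <- structure(list(samples = d$samples, plots = same),
                  class = "study_design")
  expect_equal(combo_geo_distance(c("FK", "ZY", "MQ"), d2), 0)
  # quarter great circle: (0,0) to (90,0) through an interior point
  eq <- plots
  eq$latitude <- c(0, 45, 90, rep(10, 10))
  eq$longitude <- 0
  d3 <- structure(list(samples = d$samples, plots = eq),
                  class = "study_design")
  expect_equal(combo_geo_distance(plots$plot_id[1:3], d3),
               pi / 2 * 6371, tolerance = 1e-4)
  # adding an interior plot never changes the maximum
  base <- combo_geo_distance(c("FK", "ST"), d)
  expect_equal(combo_geo_distance(c("FK", "ZY", "ST"), d), base)
})

test_that("combination evaluation produces bounded marginal explanations", {
  d <- make_study_design(stage_counts = c(A = 26, C = 8, M = 8))
  tr <- simulate_tree(60, seed = 9)
  otu <- simulate_communities(d, tr, regime_spec(
    "heterogeneous_selection", selection_strength = 3, stage_effect = 0.5,
    seed = 2))
  env <- simulate_env(d, seed = 3)[, c("salinity", "WC", "AI")]
  res <- evaluate_combination(c("FK", "ZY", "MQ"), otu, tr, d, env,
                              n_perm = 49, seed = 4)
  for (fc in c("taxonomic", "phylogenetic")) {
    r <- res$facets[[fc]]
    vals <- c(r$r2_succession, r$r2_spatial, r$r2_env)
    expect_true(all(vals >= 0 & vals <= 1, na.rm = TRUE))
    expect_false(is.na(r$r2_env_aggregate))
  }
  expect_gt(res$geo_distance_km, 0)

  # duplicated samples by stage: stage explains everything
  cnt <- matrix(0, 4, 8, dimnames = list(
    paste0("t", 1:4), paste0("x", 1:8)))
  cnt[, 1:4] <- c(10, 0, 0, 0)
  cnt[, 5:8] <- c(0, 0, 0, 10)
  dup <- otu_table(cnt)
  samples <- data.frame(sample_id = paste0("x", 1:8),
                        plot_id = rep(c("P1", "P2"), 4),
                        stage = rep(c("A", "C"), each = 4))
  plots <- data.frame(plot_id = c("P1", "P2"), latitude = c(30, 31),
                      longitude = 100, is_anchor = FALSE)
  dd <- study_design(samples, plots)
  r <- evaluate_combination(c("P1", "P2"), dup, design = dd,
                            facets = "taxonomic", n_perm = 49, seed = 1)
  expect_equal(r$facets$taxonomic$r2_succession, 1)
  expect_lt(r$facets$taxonomic$r2_spatial, 0.2)
})

test_that("environmental aggregation honours the weighting modes", {
  expect_equal(aggregate_env_r2(c(a = 0.2, b = 0.4)), 0.3)
  expect_equal(aggregate_env_r2(c(0.2, 0.4), weighting = "r2-weighted"),
               (0.2^2 + 0.4^2) / 0.6)
  expect_equal(aggregate_env_r2(c(0.2, NA, 0.4)), 0.3)
  expect_equal(aggregate_env_r2(c(0.2, 0.4), p = c(0.5, 0),
                                weighting = "significance-weighted"),
               (0.5 * 0.2 + 1 * 0.4) / 1.5)
})

test_that("driving-force slopes reduce to closed-form OLS", {
  mk <- function(dist, r2) {
    structure(list(plots = "x", k = 3, geo_distance_km = dist,
                   facets = list(taxonomic = list(
                     r2_succession = r2, r2_spatial = r2,
                     r2_env_aggregate = r2))),
              class = "combination_result")
  }
  res <- list(mk(100, 0.2), mk(200, 0.4), mk(300, 0.6))
  sl <- suppressWarnings(driving_force_slope(res, "taxonomic", "spatial"))
  expect_equal(sl$slope, 0.002, tolerance = 1e-12)
  expect_equal(sl$r_squared, 1, tolerance = 1e-12)

  flat <- list(mk(100, 0.3), mk(200, 0.3), mk(300, 0.3))
  expect_equal(suppressWarnings(
    driving_force_slope(flat, "taxonomic", "spatial"))$slope, 0,
    tolerance = 1e-12)

  neg <- list(mk(100, -0.2), mk(200, -0.4), mk(300, -0.6))
  expect_equal(suppressWarnings(
    driving_force_slope(neg, "taxonomic", "spatial"))$slope,
    -0.002, tolerance = 1e-12)

  same <- list(mk(100, 0.2), mk(100, 0.4), mk(100, 0.6))
  expect_error(driving_force_slope(same, "taxonomic", "spatial"),
               "distances equal")
  expect_error(driving_force_slope(res[1:2], "taxonomic", "spatial"),
               ">= 3")
})

test_that("subsampled framework runs are reproducible and well-formed", {
  d <- make_study_design(stage_counts = c(A = 26, C = 8, M = 8))
  tr <- simulate_tree(40, seed = 9)
  otu <- simulate_communities(d, tr, regime_spec(
    "heterogeneous_selection", selection_strength = 3, seed = 2))
  env <- simulate_env(d, seed = 3)[, c("salinity", "WC"), drop = FALSE]
  run <- function() suppressWarnings(
    sp_driving_forces(otu, tr, d, env, kmin = 3, kmax = 4, subsample = 4,
                      facets = "taxonomic", n_perm = 19, seed = 11))
  a <- run()
  b <- run()
  expect_identical(a$slopes, b$slopes)
  expect_equal(unname(a$counts), c(202, 589))
  expect_equal(nrow(a$slopes), 2 * 3)
  expect_true(all(is.finite(a$slopes$slope)))
})
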