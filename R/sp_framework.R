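#' Enumerate constrained plot combinations
#'
#' All k-subsets of the design's plots that (i) contain at least one anchor
#' plot and (ii) jointly host all three successional stages, in
#' lexicographic order of sorted plot ids. With anchors hosting all three
#' stages and every plot hosting stage A, the retained count reduces to
#' `choose(n, k) - choose(n - n_anchor, k)`.
#'
#' @param design A `"study_design"`.
#' @param k Subset size, between 3 and the number of plots.
#' @return List of character vectors (sorted plot ids).
#' @export
enumerate_combinations <- function(design, k) {
  n <- nrow(design$plots)
  if (k < 3 || k > n) stopf("k must be in [3, %d]", n)
  ids <- sort(design$plots$plot_id)
  anchors <- design$plots$plot_id[design$plots$is_anchor]
  hosted <- design$plots$hosted
  names(hosted) <- design$plots$plot_id
  combos <- utils::combn(ids, k, simplify = FALSE)
  keep <- vapply(combos, function(cmb) {
    any(cmb %in% anchors) &&
      length(unique(unlist(hosted[cmb]))) == 3L
  }, logical(1))
  combos[keep]
}

#' Maximum inter-plot great-circle distance of a combination
#'
#' The geographic extent of a combined dataset: the haversine distance (km,
#' sphere of radius 6371 km) between its two farthest plots.
#'
#' @param combination Character vector of plot ids.
#' @param design A `"study_design"` providing coordinates.
#' @return Distance in km.
#' @export
combo_geo_distance <- function(combination, design) {
  idx <- match(combination, design$plots$plot_id)
  if (anyNA(idx)) stopf("unknown plot '%s'", combination[which(is.na(idx))[1]])
  xy <- cbind(design$plots$longitude[idx], design$plots$latitude[idx])
  if (anyNA(xy)) stopf("missing coordinates")
  max(geosphere::distm(xy, fun = function(p1, p2)
    geosphere::distHaversine(p1, p2, r = 6371000))) / 1000
}

#' Aggregate per-variable environmental explanations
#'
#' @param r2 Named vector of per-variable PERMANOVA R2 (NAs dropped).
#' @param p Matching p-values (needed for `"significance-weighted"`).
#' @param weighting `"mean"` (unweighted arithmetic mean, default),
#'   `"r2-weighted"` (weights proportional to R2), or
#'   `"significance-weighted"` (weights proportional to 1 - p).
#' @return Scalar aggregate explanation.
#' @export
aggregate_env_r2 <- function(r2, p = NULL,
                             weighting = c("mean", "r2-weighted",
                                           "significance-weighted")) {
  weighting <- match.arg(weighting)
  keep <- !is.na(r2)
  r2 <- r2[keep]
  if (!length(r2)) return(NA_real_)
  w <- switch(weighting,
              mean = rep(1, length(r2)),
              `r2-weighted` = r2,
              `significance-weighted` = {
                if (is.null(p)) stopf("p-values required for significance weighting")
                1 - p[keep]
              })
  if (sum(w) == 0) w <- rep(1, length(r2))
  sum(w * r2) / sum(w)
}

#' Evaluate one plot combination
#'
#' Restricts the dataset to the combination's plots, computes the requested
#' dissimilarity facets, and runs marginal PERMANOVAs for the successional
#' factor (stage labels), the spatial factor (plot labels), and each
#' environmental variable; per-facet environmental explanations are
#' aggregated by [aggregate_env_r2()]. Samples missing a variable are
#' dropped pairwise for that variable's test only. A factor left with a
#' single level after restriction yields `NA` with a warning.
#'
#' @param combination Character vector of plot ids.
#' @param otu An [otu_table].
#' @param tree `"phylo"` (needed for the phylogenetic facet).
#' @param design A `"study_design"`.
#' @param env Environmental data frame (samples x variables) or `NULL`.
#' @param facets Which facets to compute.
#' @param n_perm Permutations per PERMANOVA.
#' @param seed Integer seed.
#' @param env_weighting Aggregation mode, see [aggregate_env_r2()].
#' @return A `"combination_result"` list: `plots`, `k`, `geo_distance_km`,
#'   and per facet `r2_succession`, `r2_spatial`, `r2_env` (per variable),
#'   `r2_env_aggregate`.
#' @export
evaluate_combination <- function(combination, otu, tree = NULL, design, env = NULL,
                                 facets = c("taxonomic", "phylogenetic"),
                                 n_perm = 999, seed = 1,
                                 env_weighting = "mean") {
  facets <- match.arg(facets, several.ok = TRUE)
  samp <- design$samples[design$samples$plot_id %in% combination, ]
  samp <- samp[samp$sample_id %in% colnames(otu), ]
  if (length(unique(samp$plot_id)) < 2 || length(unique(samp$stage)) < 2)
    stopf("combination must span >= 2 plots and >= 2 stages among sampled data")
  sub <- otu_table(unclass(otu)[, samp$sample_id, drop = FALSE])
  sub <- otu_table(sub[rowSums(sub) > 0, , drop = FALSE])

  dms <- list()
  if ("taxonomic" %in% facets) dms$taxonomic <- bray_curtis(sub)
  if ("phylogenetic" %in% facets) {
    if (is.null(tree)) stopf("tree required for the phylogenetic facet")
    dms$phylogenetic <- weighted_unifrac(sub, tree)
  }

  marginal_r2 <- function(dm, labels, what) {
    labels <- labels[match(rownames(dm), samp$sample_id)]
    if (length(unique(labels)) < 2) {
      warnf("factor '%s' has a single level in this combination", what)
      return(c(NA_real_, NA_real_))
    }
    fit <- permanova(dm, labels, n_perm = n_perm, seed = seed)
    c(fit$R2, fit$p_value)
  }

  res <- list(plots = sort(combination), k = length(combination),
              geo_distance_km = combo_geo_distance(combination, design),
              facets = list())
  for (fc in names(dms)) {
    dm <- dms[[fc]]
    succ <- marginal_r2(dm, samp$stage, "stage")
    spat <- marginal_r2(dm, samp$plot_id, "plot")
    env_r2 <- env_p <- NULL
    if (!is.null(env)) {
      vars <- colnames(env)
      env_r2 <- env_p <- stats::setNames(rep(NA_real_, length(vars)), vars)
      for (v in vars) {
        x <- env[match(rownames(dm), rownames(env)), v]
        ok <- !is.na(x)
        if (sum(ok) < 3 || length(unique(x[ok])) < 2) {
          warnf("variable '%s' unusable in this combination", v)
          next
        }
        dmv <- as_distance_matrix(dm[ok, ok, drop = FALSE])
        fit <- permanova(dmv, x[ok], n_perm = n_perm, seed = seed)
        env_r2[v] <- fit$R2
        env_p[v] <- fit$p_value
      }
    }
    res$facets[[fc]] <- list(
      r2_succession = succ[1], p_succession = succ[2],
      r2_spatial = spat[1], p_spatial = spat[2],
      r2_env = env_r2,
      r2_env_aggregate = if (is.null(env_r2)) NA_real_ else
        aggregate_env_r2(env_r2, env_p, env_weighting))
  }
  structure(res, class = "combination_result")
}

#' Driving-force slope of a factor across combinations
#'
#' Ordinary least squares of a factor's PERMANOVA R2 on the combinations'
#' geographic extent (km). The slope (R2 per km) is the driving force: a
#' positive slope means the factor explains more community variation as the
#' spatial extent of the combined dataset grows.
#'
#' @param results List of `"combination_result"` (one k).
#' @param facet `"taxonomic"` or `"phylogenetic"`.
#' @param factor One of `"successional"`, `"spatial"`, `"environmental"`.
#' @return A `"driving_force"` list: `k`, `facet`, `factor`, `slope`,
#'   `p_value`, `r_squared`, `n`.
#' @export
driving_force_slope <- function(results,
                                facet = c("taxonomic", "phylogenetic"),
                                factor = c("successional", "spatial",
                                           "environmental")) {
  facet <- match.arg(facet)
  factor <- match.arg(factor)
  field <- switch(factor, successional = "r2_succession",
                  spatial = "r2_spatial", environmental = "r2_env_aggregate")
  x <- vapply(results, function(r) r$geo_distance_km, numeric(1))
  y <- vapply(results, function(r) r$facets[[facet]][[field]], numeric(1))
  ok <- !is.na(y)
  if (sum(ok) < 3) stopf("need >= 3 combinations with non-missing R2")
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2) stopf("all geographic distances equal; slope undefined")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(k = results[[which(ok)[1]]]$k, facet = facet, factor = factor,
                 slope = unname(stats::coef(fit)[2]),
                 p_value = sm$coefficients[2, 4],
                 r_squared = sm$r.squared, n = length(x)),
            class = "driving_force")
}

#' @export
print.driving_force <- function(x, ...) {
  cat(sprintf("k=%d %s/%s: slope = %.3g R2/km (p = %.3g, R2 = %.3f, n = %d)\n",
              x$k, x$facet, x$factor, x$slope, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Run the species-pool driving-force framework
#'
#' For each subset size k, enumerates the constrained combinations
#' (optionally subsampling them with a seed), evaluates each with
#' [evaluate_combination()], and fits the per-factor driving-force slopes.
#'
#' @param otu,tree,design,env Dataset (see [evaluate_combination()]).
#' @param kmin,kmax Range of subset sizes (defaults 3 and 10).
#' @param subsample Maximum combinations evaluated per k (`Inf` = all);
#'   subsampling is a seeded simple random draw.
#' @param facets,n_perm,env_weighting Passed to [evaluate_combination()].
#' @param seed Integer master seed.
#' @return A `"sp_framework"` list: `counts` (full enumeration counts per
#'   k), `results` (per-k lists of combination results), `slopes` (data
#'   frame of slopes per k, facet, and factor).
#' @export
sp_driving_forces <- function(otu, tree = NULL, design, env = NULL,
                              kmin = 3, kmax = 10, subsample = Inf,
                              facets = c("taxonomic", "phylogenetic"),
                              n_perm = 999, env_weighting = "mean", seed = 1) {
  ks <- seq(kmin, kmax)
  counts <- stats::setNames(integer(length(ks)), ks)
  results <- list()
  slopes <- list()
  for (i in seq_along(ks)) {
    k <- ks[i]
    combos <- enumerate_combinations(design, k)
    counts[i] <- length(combos)
    if (is.finite(subsample) && length(combos) > subsample)
      combos <- with_seed(stage_seed(seed, k),
                          combos[sort(sample.int(length(combos), subsample))])
    res <- lapply(seq_along(combos), function(j)
      evaluate_combination(combos[[j]], otu, tree, design, env,
                           facets = facets, n_perm = n_perm,
                           seed = stage_seed(seed, k * 10000 + j),
                           env_weighting = env_weighting))
    results[[as.character(k)]] <- res
    for (fc in facets) for (fac in c("successional", "spatial", "environmental")) {
      if (fac == "environmental" && is.null(env)) next
      sl <- driving_force_slope(res, fc, fac)
      slopes[[length(slopes) + 1]] <- data.frame(
        k = k, facet = fc, factor = fac, slope = sl$slope,
        p_value = sl$p_value, r_squared = sl$r_squared, n = sl$n)
    }
  }
  structure(list(counts = counts, results = results,
                 slopes = do.call(rbind, slopes)),
            class = "sp_framework")
}
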