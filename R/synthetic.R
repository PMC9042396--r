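#' Default plot names of the synthetic transect
#'
#' Thirteen dryland plots named by place-name abbreviation; the four anchors
#' (Fukang, Zhangye, Minqin, Shapotou) host all three successional stages.
#' Real plot coordinates are not part of the public record, so the
#' synthetic transect is a stand-in: plots are listed in transect order
#' with the anchors spread evenly along it (positions 1, 5, 9, 13), which
#' keeps anchor membership uncorrelated with the geographic extent of a
#' plot combination.
#' @export
DEFAULT_PLOTS <- c("FK", "DH", "PL", "DQ", "ZY", "ZQ", "JC",
                   "BQ", "MQ", "LQ", "LZ", "NM", "ST")

#' @rdname DEFAULT_PLOTS
#' @export
DEFAULT_ANCHORS <- c("FK", "ZY", "MQ", "ST")

#' Generate the synthetic study design
#'
#' Places `n_plots` plots equally spaced along a meridional great-circle
#' transect whose farthest pair spans `transect_km`, assigns every plot
#' algal (A) crust samples, and confines cyanobacterial-lichen (C) and moss
#' (M) samples to the anchor plots, which therefore host all three stages.
#' Per-stage totals are met exactly; within a stage, samples are dealt
#' round-robin across the eligible plots.
#'
#' @param n_plots Number of plots (default 13).
#' @param plot_names Plot identifiers; defaults to [DEFAULT_PLOTS].
#' @param anchors Anchor plot identifiers, a subset of `plot_names`.
#' @param stage_counts Named integer vector `c(A=, C=, M=)` of per-stage
#'   sample totals; default `c(A=140, C=24, M=36)` (200 samples).
#' @param transect_km Great-circle span between the farthest plots, km.
#' @param jitter_km SD of along-transect positional jitter (0 = equal
#'   spacing; the two end plots are never jittered so the span is exact).
#' @param seed Integer seed (only used when `jitter_km > 0`).
#' @return A `"study_design"`.
#' @export
make_study_design <- function(n_plots = 13,
                              plot_names = DEFAULT_PLOTS[seq_len(n_plots)],
                              anchors = DEFAULT_ANCHORS,
                              stage_counts = c(A = 140, C = 24, M = 36),
                              transect_km = 3500,
                              jitter_km = 0,
                              seed = 1) {
  if (length(plot_names) != n_plots) stopf("need %d plot names", n_plots)
  if (!all(anchors %in% plot_names)) stopf("anchors must be among the plots")
  if (length(anchors) > n_plots) stopf("more anchors than plots")
  if (any(stage_counts <= 0)) stopf("stage counts must be positive")
  stage_counts <- stage_counts[STAGES]
  if (anyNA(stage_counts)) stopf("stage_counts must be named A, C, M")

  # equally spaced latitudes on one meridian: great-circle distance is then
  # linear in latitude, so the farthest pair spans exactly transect_km
  span_deg <- transect_km / 6371 * 180 / pi
  pos <- seq(0, 1, length.out = n_plots)
  if (jitter_km > 0 && n_plots > 2) {
    jit <- with_seed(seed, stats::rnorm(n_plots - 2, 0, jitter_km / transect_km))
    pos[2:(n_plots - 1)] <- sort(pmin(1, pmax(0, pos[2:(n_plots - 1)] + jit)))
  }
  plots <- data.frame(plot_id = plot_names,
                      latitude = 32 + pos * span_deg,
                      longitude = 100,
                      is_anchor = plot_names %in% anchors,
                      stringsAsFactors = FALSE)

  alloc <- function(total, eligible) {
    # deal `total` samples round-robin over the eligible plots
    eligible[(seq_len(total) - 1L) %% length(eligible) + 1L]
  }
  rows <- do.call(rbind, lapply(STAGES, function(st) {
    eligible <- if (st == "A") plot_names else anchors
    plot <- sort(alloc(stage_counts[[st]], eligible))
    data.frame(plot_id = plot, stage = st, stringsAsFactors = FALSE)
  }))
  rows <- rows[order(match(rows$plot_id, plot_names), rows$stage), ]
  rows$sample_id <- sprintf("%s_%s_%02d", rows$plot_id, rows$stage,
                            stats::ave(seq_len(nrow(rows)), rows$plot_id,
                                       rows$stage, FUN = seq_along))
  study_design(rows[, c("sample_id", "plot_id", "stage")], plots)
}

#' Simulate a two-clade phylogeny
#'
#' A random bifurcating rooted tree whose root splits the tips into two deep
#' sister clades (an SG1-like and an SG2-like lineage), mirroring a
#' Nitrososphaeraceae-dominated versus Haloarchaea-dominated pool. Each
#' clade is a random coalescent tree (exponentially distributed
#' coalescence intervals, so most splits are recent and every tip has
#' close relatives); the two clade stems get length `stem_length`, which
#' sets how much deeper between-clade divergences are than within-clade
#' ones.
#'
#' @param n_taxa Total number of tips (>= 4).
#' @param clade_split Fraction of tips in the first (SG1-like) clade.
#' @param stem_length Branch length of each clade stem.
#' @param seed Integer seed; the same seed gives an identical tree.
#' @return A rooted `"phylo"` with tips `SG1_###` / `SG2_###`.
#' @export
simulate_tree <- function(n_taxa, clade_split = 0.5, stem_length = 3, seed = 1) {
  if (n_taxa < 4) stopf("need at least 4 taxa (2 per clade)")
  n1 <- max(2L, min(n_taxa - 2L, round(clade_split * n_taxa)))
  n2 <- n_taxa - n1
  with_seed(seed, {
    t1 <- ape::rcoal(n1, tip.label = sprintf("SG1_%03d", seq_len(n1)))
    t2 <- ape::rcoal(n2, tip.label = sprintf("SG2_%03d", seq_len(n2)))
    nwk <- sprintf("(%s:%g,%s:%g);",
                   sub(";$", "", ape::write.tree(t1)), stem_length,
                   sub(";$", "", ape::write.tree(t2)), stem_length)
    validate_tree(ape::read.tree(text = nwk))
  })
}

#' Environmental variable blocks of the synthetic gradient
#'
#' The salinity-related block loads positively on the latent transect
#' gradient, the non-salinity block negatively, and the remaining variables
#' of the field catalogue are gradient-free noise.
#' @export
ENV_SALINITY_BLOCK <- c("salinity", "PO4", "silt", "WS", "pH", "AI",
                        "MAT", "MASD")

#' @rdname ENV_SALINITY_BLOCK
#' @export
ENV_NONSALINITY_BLOCK <- c("FvFm", "NH4", "ORP", "MAP", "Alt", "WC")

ENV_NEUTRAL_VARS <- c("TH", "Chla", "Scyt", "EPS", "BChla", "TN", "TP",
                      "TOC", "ALPT", "bGC", "ALP")

#' Latent environmental gradient of a design
#'
#' Plot position along the transect rescaled to `[-1, 1]` (south to north),
#' replicated per sample.
#' @param design A `"study_design"`.
#' @return Named numeric vector over samples.
#' @export
design_gradient <- function(design) {
  lat <- design$plots$latitude
  g <- if (diff(range(lat)) == 0) rep(0, length(lat)) else
    2 * (lat - min(lat)) / diff(range(lat)) - 1
  names(g) <- design$plots$plot_id
  out <- g[design$samples$plot_id]
  names(out) <- design$samples$sample_id
  out
}

#' Simulate environmental variables along the transect gradient
#'
#' Each salinity-block variable is `+loading * gradient + noise`, each
#' non-salinity-block variable `-loading * gradient + noise`, and the
#' remaining field-catalogue variables are pure noise, so the two blocks are
#' anti-correlated and both track plot position.
#'
#' @param design A `"study_design"`.
#' @param loading Gradient loading (default 1).
#' @param noise_sd Gaussian noise SD (default 0.3).
#' @param seed Integer seed.
#' @return Numeric data frame, samples x ~25 variables.
#' @export
simulate_env <- function(design, loading = 1, noise_sd = 0.3, seed = 1) {
  g <- design_gradient(design)
  n <- length(g)
  vars <- c(ENV_SALINITY_BLOCK, ENV_NONSALINITY_BLOCK, ENV_NEUTRAL_VARS)
  sign <- c(rep(1, length(ENV_SALINITY_BLOCK)),
            rep(-1, length(ENV_NONSALINITY_BLOCK)),
            rep(0, length(ENV_NEUTRAL_VARS)))
  with_seed(seed, {
    m <- vapply(seq_along(vars), function(j)
      sign[j] * loading * g + stats::rnorm(n, 0, noise_sd),
      numeric(n))
  })
  colnames(m) <- vars
  env <- as.data.frame(m)
  rownames(env) <- names(g)
  env
}

REGIMES <- c("heterogeneous_selection", "homogeneous_selection",
             "homogenizing_dispersal", "dispersal_limitation_drift", "drift")

#' Specify a community-assembly regime for simulation
#'
#' Bundles the generator knobs for [simulate_communities()]. Defaults are
#' per regime: `selection_strength` 10 for homogeneous selection and 30
#' for heterogeneous selection (0 otherwise); `migration_rate` 0.97 for
#' homogenizing dispersal, 0 for dispersal limitation, irrelevant
#' otherwise; `community_size` 400 individuals per sample; `pool_sdlog`
#' 1.5 (log-normal unevenness of the dispersal-regime species pools);
#' demographic noise `retention` 0.5 and `sdlog` 0.3 under selection.
#'
#' @param regime One of `"heterogeneous_selection"`,
#'   `"homogeneous_selection"`, `"homogenizing_dispersal"`,
#'   `"dispersal_limitation_drift"`, `"drift"`.
#' @param selection_strength Non-negative Gaussian niche-filter strength on
#'   the standardized Brownian trait.
#' @param migration_rate Fraction of each community drawn from the shared
#'   regional occurrence rather than the plot-local pool, in `[0, 1]`.
#' @param community_size Individuals per sample.
#' @param pool_sdlog sdlog of log-normal pool weights for dispersal regimes.
#' @param demographic_retention Per-sample Bernoulli retention probability
#'   of each eligible taxon under the selection regimes: which of the
#'   ecologically equivalent close relatives establish varies from sample
#'   to sample, producing the taxon turnover that phylogenetic turnover
#'   statistics require (with no turnover, shared taxa sit at nearest-taxon
#'   distance zero in both the observed and the null communities and the
#'   selection signal is invisible).
#' @param demographic_sdlog sdlog of the mild log-normal abundance noise
#'   multiplying the niche filter; kept small so community abundances stay
#'   even, which tightens the null distribution of betaMNTD.
#' @param stage_effect Size of a fixed successional imprint on composition
#'   (default 0 = stages do not influence composition). Under the
#'   selection regimes it shifts each stage's trait optimum by
#'   `stage_effect * c(A = 0, C = +1, M = -1)` trait SDs; under the other
#'   regimes it is the sdlog of a fixed per-stage log-normal tilt on taxon
#'   weights. A positive value gives the successional factor a genuine,
#'   constant-magnitude imprint that spatial turnover progressively
#'   dilutes as geographic extent grows — the distance-decay scenario for
#'   the species-pool framework.
#' @param seed Integer seed.
#' @return A `"regime_spec"` list.
#' @export
regime_spec <- function(regime,
                        selection_strength = NULL,
                        migration_rate = NULL,
                        community_size = 400,
                        pool_sdlog = 1.5,
                        demographic_retention = 0.5,
                        demographic_sdlog = 0.3,
                        stage_effect = 0,
                        seed = 1) {
  regime <- match.arg(regime, REGIMES)
  selection_strength <- selection_strength %||%
    switch(regime, heterogeneous_selection = 30, homogeneous_selection = 10, 0)
  migration_rate <- migration_rate %||%
    switch(regime, homogenizing_dispersal = 0.97,
           dispersal_limitation_drift = 0, 0)
  if (selection_strength < 0) stopf("selection_strength must be >= 0")
  if (migration_rate < 0 || migration_rate > 1)
    stopf("migration_rate must be in [0, 1]")
  if (community_size < 1) stopf("community_size must be positive")
  structure(list(regime = regime, selection_strength = selection_strength,
                 migration_rate = migration_rate,
                 community_size = as.integer(community_size),
                 pool_sdlog = pool_sdlog,
                 demographic_retention = demographic_retention,
                 demographic_sdlog = demographic_sdlog,
                 stage_effect = stage_effect,
                 seed = as.integer(seed)),
            class = "regime_spec")
}

#' Simulate communities under a known assembly regime
#'
#' Builds one OTU count table over the design's samples. A niche trait is
#' evolved on the tree by Brownian motion and standardized. Regimes:
#'
#' * selection regimes weight taxa by
#'   `exp(-selection_strength * (trait - optimum)^2)`, with one shared
#'   optimum (homogeneous selection, optimum 0) or an optimum tracking each
#'   sample's transect gradient over `[-2, 2]` trait SDs (heterogeneous
#'   selection); each sample is an independent multinomial of
#'   `community_size` individuals from its weights.
#' * dispersal regimes draw plot-local log-normal pools plus one shared
#'   regional occurrence (a single realized multinomial community of
#'   `migration_rate * community_size` individuals, copied into every
#'   sample — the "mass" that disperses); the remaining individuals are an
#'   independent multinomial from the plot-local pool. Migration near 1
#'   makes samples near-identical; migration near 0 leaves each plot its own
#'   pool.
#' * drift draws every sample independently from equal regional weights.
#'
#' @param design A `"study_design"`.
#' @param tree A `"phylo"` over the taxon pool.
#' @param spec A `"regime_spec"`.
#' @return An [otu_table] (taxa x samples) with attribute `"trait"` (the
#'   standardized niche trait) and `"regime"`.
#' @export
simulate_communities <- function(design, tree, spec) {
  if (!inherits(spec, "regime_spec")) stopf("spec must be a regime_spec")
  n_taxa <- length(tree$tip.label)
  if (n_taxa < 20) stopf("need >= 20 tree tips for stable phylogenetic signal")
  samples <- design$samples$sample_id
  plots <- design$samples$plot_id
  N <- spec$community_size
  with_seed(spec$seed, {
    trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
    trait <- (trait - mean(trait)) / stats::sd(trait)
    trait <- trait[tree$tip.label]
    g <- design_gradient(design)
    # fixed per-stage tilt on taxon weights (off at stage_effect = 0)
    stage_of <- stats::setNames(design$samples$stage, samples)
    tilt <- if (spec$stage_effect > 0)
      vapply(STAGES, function(s) stats::rlnorm(n_taxa, 0, spec$stage_effect),
             numeric(n_taxa))
    else matrix(1, n_taxa, 3, dimnames = list(NULL, STAGES))
    colnames(tilt) <- STAGES
    counts <- switch(
      spec$regime,
      drift = {
        vapply(samples, function(s)
          stats::rmultinom(1, N, tilt[, stage_of[[s]]])[, 1],
          numeric(n_taxa))
      },
      homogeneous_selection = ,
      heterogeneous_selection = {
        # the Brownian trait is bimodal across the two deep clades, so the
        # shared optimum sits at the densest trait mode (inside a clade);
        # an optimum midway between the clades would select a
        # phylogenetically mixed set
        dens <- stats::density(trait)
        opt_shared <- dens$x[which.max(dens$y)]
        stage_shift <- c(A = 0, C = 1, M = -1) * spec$stage_effect
        vapply(samples, function(s) {
          opt <- (if (spec$regime == "homogeneous_selection") opt_shared
                  else 2 * g[[s]]) + stage_shift[[stage_of[[s]]]]
          # niche filter times per-sample demographic noise: which close
          # relatives establish inside the filtered clade varies sample to
          # sample (Bernoulli retention), with mild abundance noise
          w <- exp(-spec$selection_strength * (trait - opt)^2) *
            stats::rbinom(n_taxa, 1, spec$demographic_retention) *
            stats::rlnorm(n_taxa, 0, spec$demographic_sdlog)
          if (sum(w) == 0) w <- rep(1, n_taxa)
          stats::rmultinom(1, N, w)[, 1]
        }, numeric(n_taxa))
      },
      homogenizing_dispersal = ,
      dispersal_limitation_drift = {
        regional_w <- stats::rlnorm(n_taxa, 0, spec$pool_sdlog)
        local_w <- vapply(unique(plots), function(p)
          stats::rlnorm(n_taxa, 0, spec$pool_sdlog), numeric(n_taxa))
        n_shared <- round(spec$migration_rate * N)
        shared <- if (n_shared > 0)
          stats::rmultinom(1, n_shared, regional_w)[, 1] else numeric(n_taxa)
        vapply(seq_along(samples), function(i) {
          own <- if (N - n_shared > 0)
            stats::rmultinom(1, N - n_shared,
                             local_w[, plots[i]] *
                               tilt[, stage_of[[samples[i]]]])[, 1]
          else numeric(n_taxa)
          shared + own
        }, numeric(n_taxa))
      },
      stopf("unknown regime '%s'", spec$regime))
    colnames(counts) <- samples
    rownames(counts) <- tree$tip.label
    out <- otu_table(counts)
    attr(out, "trait") <- trait
    attr(out, "regime") <- spec$regime
    out
  })
}

#' Write a complete synthetic dataset to a directory
#'
#' Emits `otu.tsv`, `tree.nwk`, `design.tsv`, `env.tsv`, and
#' `provenance.json` (all generator parameters and seeds).
#'
#' @param dir Output directory (created if needed).
#' @param spec A `"regime_spec"`; its seed drives tree, environment, and
#'   communities through derived stage seeds.
#' @param n_taxa Tips in the simulated tree.
#' @param design Optional design; defaults to [make_study_design()].
#' @return Invisibly, the list of written paths.
#' @export
simulate_dataset <- function(dir, spec = regime_spec("drift"), n_taxa = 150,
                             design = make_study_design()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tree <- simulate_tree(n_taxa, seed = stage_seed(spec$seed, 1))
  env <- simulate_env(design, seed = stage_seed(spec$seed, 2))
  otu <- simulate_communities(design, tree, spec)
  paths <- list(otu = file.path(dir, "otu.tsv"),
                tree = file.path(dir, "tree.nwk"),
                design = file.path(dir, "design.tsv"),
                env = file.path(dir, "env.tsv"),
                provenance = file.path(dir, "provenance.json"))
  write_otu_table(otu, paths$otu)
  ape::write.tree(tree, paths$tree)
  write_design(design, paths$design)
  write_env(env, paths$env)
  jsonlite::write_json(list(stage = "simulate", parameters = unclass(spec),
                            n_taxa = n_taxa,
                            n_samples = nrow(design$samples)),
                       paths$provenance, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
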