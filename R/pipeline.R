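#' Default pipeline configuration
#'
#' Returns the full configuration list accepted by [run_pipeline()], with
#' every stage's parameters at its documented default. Any subset of fields
#' may be overridden via `...` (named lists are merged one level deep).
#'
#' @param ... Named overrides, e.g. `simulate = list(n_taxa = 60)`.
#' @return Named list of stage configurations.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1,
    out_dir = "crustpool_run",
    simulate = list(regime = "drift", n_taxa = 150, community_size = 400,
                    n_plots = 13, transect_km = 3500),
    stats = list(n_perm = 999),
    spframework = list(kmin = 3, kmax = 10, subsample = Inf, n_perm = 999,
                       env_weighting = "mean", run = TRUE),
    assembly = list(n_null = 999, run = TRUE),
    network = list(method = "spearman", min_prevalence = 0.2,
                   r_threshold = 0.8, p_max = 0.05, run = TRUE))
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[nm]])
    else cfg[[nm]] <- dots[[nm]]
  }
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file path.
#' @return Configuration list (defaults filled in).
#' @export
read_config <- function(path) {
  do.call(default_config, yaml::read_yaml(path))
}

write_provenance <- function(dir, stage, params) {
  jsonlite::write_json(c(list(stage = stage, timestamp = format(Sys.time())),
                         params),
                       file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> dissimilarities -> permutation statistics ->
#' species-pool framework -> assembly partitioning -> co-occurrence network
#' on a synthetic dataset, writing each stage's tables plus a JSON
#' provenance block into `config$out_dir`. One master seed deterministically
#' derives every stage seed (see [stage_seed()]), so identical
#' configurations give byte-identical outputs.
#'
#' @param config Configuration list from [default_config()] /
#'   [read_config()], or a YAML path.
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config = default_config()) {
  if (is.character(config)) config <- read_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # -- simulate ------------------------------------------------------------
  sim <- config$simulate
  design <- make_study_design(n_plots = sim$n_plots,
                              transect_km = sim$transect_km,
                              seed = stage_seed(seed, 1))
  spec <- regime_spec(sim$regime, community_size = sim$community_size,
                      seed = stage_seed(seed, 2))
  paths <- simulate_dataset(config$out_dir, spec, n_taxa = sim$n_taxa,
                            design = design)
  otu <- read_otu_table(paths$otu)
  tree <- read_newick(paths$tree)
  env <- read_env(paths$env, design)
  write_provenance(config$out_dir, "simulate",
                   list(parameters = unclass(spec), n_taxa = sim$n_taxa,
                        seed = seed))

  # -- dissimilarities -----------------------------------------------------
  dm_tax <- bray_curtis(otu)
  dm_phy <- weighted_unifrac(otu, tree)
  write_distance_matrix(dm_tax, file.path(config$out_dir, "dm_taxonomic.tsv"))
  write_distance_matrix(dm_phy, file.path(config$out_dir, "dm_phylogenetic.tsv"))
  write_provenance(config$out_dir, "dissim",
                   list(facets = c("taxonomic", "phylogenetic"),
                        transform = "relative", normalized = TRUE))

  # -- permutation statistics ----------------------------------------------
  np <- config$stats$n_perm
  stage_lab <- stats::setNames(design$samples$stage, design$samples$sample_id)
  plot_lab <- stats::setNames(design$samples$plot_id, design$samples$sample_id)
  env_dist <- as_distance_matrix(as.matrix(stats::dist(scale(env))))
  stats_tbl <- do.call(rbind, lapply(
    list(list("permanova_stage", permanova(dm_tax, stage_lab, np,
                                           stage_seed(seed, 10))),
         list("permanova_plot", permanova(dm_tax, plot_lab, np,
                                          stage_seed(seed, 11))),
         list("anosim_stage", anosim(dm_tax, stage_lab, np,
                                     stage_seed(seed, 12))),
         list("mantel_env", mantel(dm_tax, env_dist, n_perm = np,
                                   seed = stage_seed(seed, 13)))),
    function(x) data.frame(test = x[[1]], statistic = x[[2]]$statistic,
                           R2 = x[[2]]$R2, p_value = x[[2]]$p_value)))
  utils::write.table(stats_tbl, file.path(config$out_dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config$out_dir, "stats", list(n_perm = np, seed = seed))

  # -- species-pool framework ----------------------------------------------
  spf <- NULL
  if (isTRUE(config$spframework$run)) {
    sp <- config$spframework
    spf <- sp_driving_forces(otu, tree, design, env, kmin = sp$kmin,
                             kmax = sp$kmax, subsample = sp$subsample,
                             n_perm = sp$n_perm,
                             env_weighting = sp$env_weighting,
                             seed = stage_seed(seed, 20))
    utils::write.table(spf$slopes,
                       file.path(config$out_dir, "driving_forces.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(config$out_dir, "spframework",
                     c(sp[c("kmin", "kmax", "n_perm", "env_weighting")],
                       list(subsample = if (is.finite(sp$subsample))
                         sp$subsample else "all",
                         counts = as.list(spf$counts), seed = seed)))
  }

  # -- assembly ------------------------------------------------------------
  asm <- NULL
  if (isTRUE(config$assembly$run)) {
    asm <- assembly_partition(otu, tree, n_null = config$assembly$n_null,
                              seed = stage_seed(seed, 30),
                              groups = stage_lab)
    utils::write.table(asm$pairs, file.path(config$out_dir, "assembly.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_provenance(config$out_dir, "assembly",
                     list(n_null = config$assembly$n_null, seed = seed,
                          n_excluded = asm$n_excluded,
                          proportions = as.list(asm$proportions)))
  }

  # -- network -------------------------------------------------------------
  net_out <- NULL
  if (isTRUE(config$network$run)) {
    nw <- config$network
    net_out <- tryCatch({
      corr <- correlation_matrix(otu, method = nw$method,
                                 min_prevalence = nw$min_prevalence)
      net <- build_network(corr, r_threshold = nw$r_threshold,
                           p_max = nw$p_max)
      summ <- topology_summary(net)
      roles <- zi_pi(net)
      utils::write.table(net$edges, file.path(config$out_dir, "edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(roles$roles,
                         file.path(config$out_dir, "node_roles.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(metric = names(unclass(summ)),
                   value = unlist(unclass(summ))),
        file.path(config$out_dir, "network_summary.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_provenance(config$out_dir, "network",
                       c(nw[c("method", "min_prevalence", "r_threshold",
                              "p_max")], list(seed = seed)))
      list(network = net, summary = summ, roles = roles)
    }, error = function(e) {
      warnf("network stage skipped: %s", conditionMessage(e))
      NULL
    })
  }

  invisible(list(design = design, otu = otu, tree = tree, env = env,
                 dm_taxonomic = dm_tax, dm_phylogenetic = dm_phy,
                 stats = stats_tbl, sp_framework = spf, assembly = asm,
                 network = net_out, config = config))
}
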