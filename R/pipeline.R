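#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end synthetic analysis. Defaults
#' emulate the study conditions: 105 island squamate species on a dated
#' 100-Myr phylogeny, a mainland plus six-island basin, and the three
#' resistance scenarios M1-M3.
#'
#' @param n_species number of species (tree tips).
#' @param world a [world_config()].
#' @param p_occupy per-island occupancy probability.
#' @param p_endemic probability a species is an island endemic.
#' @param birth_rate,tree_height Yule simulation parameters (Myr scale).
#' @param scenarios resistance scenarios to run.
#' @param depth_threshold M2 barrier / shallow-travel threshold (m).
#' @param n_perm permutations for Blomberg's K.
#' @param seed master integer seed; stage seeds are derived as
#'   `seed * 10 + stage`.
#' @param out_dir optional output directory; when set, all tables, the
#'   grid, the tree and a JSON run manifest are written there.
#' @export
pipeline_config <- function(n_species = 105, world = world_config(),
                            p_occupy = 0.4, p_endemic = 0.3,
                            birth_rate = 0.1, tree_height = 100,
                            scenarios = c("M1", "M2", "M3"),
                            depth_threshold = -150, n_perm = 999,
                            seed = 1L, out_dir = NULL) {
  structure(list(n_species = n_species, world = world,
                 p_occupy = p_occupy, p_endemic = p_endemic,
                 birth_rate = birth_rate, tree_height = tree_height,
                 scenarios = scenarios, depth_threshold = depth_threshold,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full dispersal-signal analysis on a synthetic archipelago
#'
#' Orchestrates every stage: world generation, the three resistance
#' surfaces, per-species travel chains and path descriptors, the
#' direction-free minimum tree, the normality-driven log transform,
#' correlation PCA, phylogenetic-signal estimation (lambda and K, with
#' scenario uncertainty and snake/lizard groups), and per-descriptor PGLS
#' over the eight covariance structures ranked by AIC weight.
#'
#' Species whose travel chain is empty (endemics occupying only their
#' origin island) are excluded from the comparative analyses as
#' incomplete cases. Regression and ordination responses are the
#' scenario means of the (transformed) descriptors; scenario uncertainty
#' is propagated in the signal tables instead.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `world`, `tree`, `occupancy`,
#'   `traits`, `metrics` (species x scenario descriptors), `transform`
#'   (transform log), `pca`, `signal`, `signal_groups`, `pgls`
#'   (per-descriptor comparison and best fit), `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", what,
                   conditionMessage(e)), call. = FALSE))
  }

  world <- stage("world", make_world(config$world))
  tree <- stage("tree", simulate_tree(config$n_species, config$birth_rate,
                                      seed = seed * 10L + 1L,
                                      height = config$tree_height))
  occ <- stage("occupancy",
               assign_occupancy(world$sites, tree, config$p_occupy,
                                seed = seed * 10L + 2L,
                                p_endemic = config$p_endemic))
  traits <- stage("traits",
                  simulate_species_traits(tree, seed = seed * 10L + 3L))
  traits$is_endemic <- occ$is_endemic[traits$species]

  # direction-free minimum tree, per species (scenario-free)
  sp <- tree$tip.label
  mst_km <- stage("minimum_tree", vapply(sp, function(s) {
    occupied <- colnames(occ$matrix)[occ$matrix[s, ] == 1]
    ids <- unique(c(occ$origin[[s]], occupied))
    if (length(ids) < 2) return(NA_real_)
    minimum_tree(world$sites, ids)$total_km
  }, numeric(1)))

  # scenario travel chains and descriptors
  metrics <- stage("paths", {
    rows <- list()
    for (scen in config$scenarios) {
      cfg <- resistance_config(scen,
                               depth_threshold = config$depth_threshold)
      res <- build_resistance(world$grid, cfg)
      cache <- site_cost_cache(res, world$sites)
      for (s in sp) {
        occupied <- colnames(occ$matrix)[occ$matrix[s, ] == 1]
        chain <- build_travel_chain(res, occ$origin[[s]], occupied,
                                    world$sites, cache = cache)
        m <- path_metrics(chain, mst_km[[s]],
                          depth_threshold = config$depth_threshold)
        m$species <- s; m$scenario <- scen
        rows[[length(rows) + 1L]] <- m
      }
    }
    do.call(rbind, rows)
  })
  metric_vars <- c("minimum_tree", "total_travel", "average_travel",
                   "max_single_travel", "average_depth", "max_depth",
                   "prop_travel_150")
  metrics <- metrics[, c("species", "scenario", metric_vars, "n_travels",
                         "n_unreachable", "all_land", "empty_chain")]
  rownames(metrics) <- NULL

  complete <- stats::aggregate(empty_chain ~ species, metrics,
                               function(x) !any(x))
  keep_sp <- complete$species[complete$empty_chain &
                                !is.na(mst_km[complete$species])]
  analysis <- metrics[metrics$species %in% keep_sp,
                      c("species", "scenario", metric_vars)]

  tr_res <- stage("transform", normality_transform(analysis))
  tab <- tr_res$table

  # scenario means per species for ordination and regression
  mean_tab <- stats::aggregate(tab[, metric_vars], by =
                                 list(species = tab$species), FUN = mean)
  tree_kept <- ape::keep.tip(tree, keep_sp)
  mean_tab <- mean_tab[match(tree_kept$tip.label, mean_tab$species), ]

  pca <- stage("pca", {
    sds <- vapply(mean_tab[, metric_vars], stats::sd, numeric(1))
    metric_pca(mean_tab[, c("species", metric_vars[sds > 0])])
  })

  sig_lambda <- stage("signal_lambda",
                      signal_with_model_uncertainty(tab, tree, "lambda",
                                                    variables = metric_vars))
  sig_K <- stage("signal_K",
                 signal_with_model_uncertainty(tab, tree, "K",
                                               variables = metric_vars,
                                               n_perm = config$n_perm,
                                               seed = seed * 10L + 4L))
  signal <- rbind(sig_lambda, sig_K)

  groups <- stats::setNames(ifelse(traits$is_snake, "snakes", "lizards"),
                            traits$species)
  signal_groups <- stage("signal_groups", {
    out <- lapply(metric_vars, function(v) {
      y <- stats::setNames(mean_tab[[v]], mean_tab$species)
      g <- groupwise_signal(y, tree_kept, groups,
                            n_perm = config$n_perm,
                            seed = seed * 10L + 5L)
      g$variable <- v
      g
    })
    do.call(rbind, out)
  })

  # regression stage
  cent <- stage("centroids", species_centroid(occ, world$sites))
  iso <- stage("isolation", phylo_isolation(tree))
  traits_full <- merge(merge(traits, cent, by = "species"),
                       iso, by = "species")
  traits_full <- traits_full[match(tree_kept$tip.label,
                                   traits_full$species), ]
  X <- stage("design", build_design(traits_full))
  pgls <- stage("pgls", {
    out <- lapply(metric_vars, function(v) {
      y <- stats::setNames(mean_tab[[v]], mean_tab$species)
      fs <- fit_pgls_set(y, X, tree_kept)
      best <- attr(fs$comparison, "best")
      list(variable = v, comparison = fs$comparison,
           best_structure = best, best_fit = fs$fits[[best]])
    })
    stats::setNames(out, metric_vars)
  })

  manifest <- list(
    package = "islandisp",
    version = as.character(utils::packageVersion("islandisp")),
    seed = seed,
    n_species = config$n_species,
    n_species_analysed = length(keep_sp),
    scenarios = config$scenarios,
    world = config$world[c("n_rows", "n_cols", "cell_size",
                           "mainland_width", "channel_depth",
                           "sea_base_depth")],
    p_occupy = config$p_occupy, p_endemic = config$p_endemic,
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  result <- structure(list(world = world, tree = tree, occupancy = occ,
                           traits = traits_full, metrics = metrics,
                           analysis_species = keep_sp,
                           transform = tr_res$log, mean_metrics = mean_tab,
                           pca = pca, signal = signal,
                           signal_groups = signal_groups, pgls = pgls,
                           manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config)
  result
}

write_csv_stable <- function(df, path) {
  utils::write.csv(format(df, digits = 12, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = TRUE)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(config$out_dir, f)
  write_esri_ascii(result$world$grid, p("grid.asc"))
  write_csv_stable(result$world$sites, p("sites.csv"))
  ape::write.tree(result$tree, p("tree.nwk"))
  occ_df <- data.frame(species = rownames(result$occupancy$matrix),
                       result$occupancy$matrix,
                       origin = result$occupancy$origin,
                       is_endemic = result$occupancy$is_endemic,
                       check.names = FALSE)
  write_csv_stable(occ_df, p("occupancy.csv"))
  write_csv_stable(result$traits, p("traits.csv"))
  write_csv_stable(result$metrics, p("metrics.csv"))
  write_csv_stable(result$transform, p("transform_log.csv"))
  write_csv_stable(result$signal, p("signal.csv"))
  write_csv_stable(result$signal_groups, p("signal_groups.csv"))
  sel <- do.call(rbind, lapply(result$pgls, function(e) {
    d <- e$comparison; d$variable <- e$variable; d
  }))
  write_csv_stable(sel, p("pgls_selection.csv"))
  best <- do.call(rbind, lapply(result$pgls, function(e) {
    d <- e$best_fit$coefficients
    d$variable <- e$variable; d$structure <- e$best_structure
    d$R2 <- e$best_fit$R2; d$AIC <- e$best_fit$AIC
    d
  }))
  write_csv_stable(best, p("pgls_best.csv"))
  load_df <- data.frame(variable = rownames(result$pca$loadings),
                        result$pca$loadings, check.names = FALSE)
  write_csv_stable(load_df, p("pca_loadings.csv"))
  sc_df <- data.frame(species = rownames(result$pca$scores),
                      result$pca$scores, check.names = FALSE)
  write_csv_stable(sc_df, p("pca_scores.csv"))
  prop_df <- data.frame(axis = names(result$pca$proportion),
                        proportion = result$pca$proportion,
                        cumulative = result$pca$cumulative)
  write_csv_stable(prop_df, p("pca_variance.csv"))
  jsonlite::write_json(result$manifest, p("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d species (%d analysed), scenarios %s\n",
              length(x$tree$tip.label), length(x$analysis_species),
              paste(unique(x$metrics$scenario), collapse = "/")))
  cat(sprintf("  PCA: PC1 %.3f, PC2 %.3f (cumulative %.3f)\n",
              x$pca$proportion[1], x$pca$proportion[2],
              x$pca$cumulative[2]))
  lam <- x$signal[x$signal$statistic == "lambda", ]
  cat(sprintf("  headline lambda range: %.3f-%.3f\n",
              min(lam$estimate), max(lam$estimate)))
  best <- vapply(x$pgls, function(e) e$best_structure, character(1))
  cat("  best PGLS structure per descriptor:",
      paste(sprintf("%s=%s", names(best), best), collapse = ", "), "\n")
  invisible(x)
}
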