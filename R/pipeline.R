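#' Default pipeline configuration
#'
#' A nested list describing one end-to-end synthetic run. Every stochastic
#' stage derives its seed deterministically from the global `seed` (stage
#' seeds are `seed + a fixed per-stage offset`), so one integer reproduces
#' the whole run. The configuration round-trips through YAML unchanged.
#'
#' @param seed Global integer seed.
#' @param outdir Output directory for stage artifacts.
#' @param mode `"synthetic"` (default) or `"raster"` (read a landscape
#'   written by [write_landscape()] from `landscape_dir`).
#' @return A `"run_config"` list.
#' @export
default_config <- function(seed = 1L, outdir = tempfile("edge_run_"),
                           mode = "synthetic") {
  structure(list(
    mode = mode,
    seed = as.integer(seed),
    outdir = outdir,
    landscape_dir = NULL,
    landscape = list(n_cells = c(4, 5), cell_px = 96, resolution = 30,
                     beta0 = 50, beta1 = 50, depth_star = 300,
                     noise_sd_white = 15, noise_sd_spatial = 8,
                     noise_range_spatial = 120,
                     clearings_per_cell = 12, clearing_px = 12,
                     beta1_from_covariates = TRUE,
                     attribution_noise_sd = 5),
    sampling = list(n_per_cell = 500),
    filters = list(min_points = 20, near_frac = 0.03, near_dist = 100,
                   exclude_within = 0),
    regression = list(k = 8, alpha = 0.05, nperm = 199, max_vectors = 50,
                      response = "biomass", tail_fraction = 0.025),
    attribution = list(tuning_budget = 10, buffer_radii = c(0, 1, 2, 5),
                       run_buffered_cv = FALSE),
    accounting = list(percentile = 0.9, mode = "top", min_points = 5),
    biomes = list(labels = c("tropical", "temperate", "boreal"))),
    class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `"run_config"` list.
#' @return `read_config()` returns the configuration; `write_config()` the
#'   path, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  for (nm in names(cfg)) {
    if (is.null(cfg[[nm]])) next
    if (is.list(base[[nm]]) && is.list(cfg[[nm]])) {
      for (sub in names(cfg[[nm]])) {
        if (!is.null(cfg[[nm]][[sub]]))
          base[[nm]][[sub]] <- cfg[[nm]][[sub]]
      }
    } else {
      base[[nm]] <- cfg[[nm]]
    }
  }
  base$seed <- as.integer(base$seed)
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11L, sample = 23L, fit = 37L, attribute = 53L,
               account = 71L, report = 89L)
  config$seed + offsets[[stage]]
}

write_table <- function(df, outdir, name) {
  utils::write.csv(df, file.path(outdir, paste0(name, ".csv")),
                   row.names = FALSE)
}

read_table <- function(outdir, name) {
  f <- file.path(outdir, paste0(name, ".csv"))
  if (!file.exists(f))
    stop("missing checkpoint '", name, "': run the earlier stages first")
  utils::read.csv(f)
}

# Vertical biome stripes over the cell grid: cells are split into
# equal-width longitude bands, one per label. Cells never straddle a
# stripe boundary when the cell count per row is a multiple of the number
# of labels; otherwise the straddling flag marks boundary cells.
assign_biomes <- function(cells, labels) {
  xmid <- (cells$xmin + cells$xmax) / 2
  breaks <- seq(min(cells$xmin), max(cells$xmax),
                length.out = length(labels) + 1)
  idx <- pmin(findInterval(xmid, breaks, rightmost.closed = TRUE),
              length(labels))
  lo <- findInterval(cells$xmin + 1e-9, breaks, rightmost.closed = TRUE)
  hi <- findInterval(cells$xmax - 1e-9, breaks, rightmost.closed = TRUE)
  data.frame(cell_id = cells$cell_id, biome = labels[idx],
             straddling = lo != hi)
}

#' Run the edge-effect pipeline
#'
#' Executes the requested stages in order: `simulate` (synthetic landscape
#' + covariates with planted effects, or raster ingest), `sample` (grid
#' cells + random points), `fit` (cell filters, spatially filtered
#' regressions, trimming, classification, inverse-CV weighted summaries),
#' `attribute` (collinearity screen, weighted XGBoost, SHAP, optional
#' buffered LOO), `account` (depth of edge influence, counterfactual
#' missing biomass, biome/global totals) and `report` (summary tables +
#' plots). Each stage writes CSV/JSON artifacts into `config$outdir` and
#' later stages read them back, so any stage can be re-run from its
#' checkpoints. A failing stage stops with the stage name in the error.
#'
#' @param config A `"run_config"`, see [default_config()].
#' @param stages Character vector of stages to run (default all, in
#'   canonical order).
#' @return The output directory, invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "sample", "fit",
                                    "attribute", "account", "report")) {
  all_stages <- c("simulate", "sample", "fit", "attribute", "account",
                  "report")
  stages <- all_stages[all_stages %in% stages]
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(outdir, "config.yaml")
  write_config(config, cfg_path)
  meta <- list(config_md5 = unname(tools::md5sum(cfg_path)),
               package_version = as.character(
                 utils::packageVersion("forestedge")),
               stages = stages)
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE)
  for (stage in stages) {
    t0 <- Sys.time()
    message("stage ", stage, " ...")
    tryCatch(
      switch(stage,
             simulate = stage_simulate(config),
             sample = stage_sample(config),
             fit = stage_fit(config),
             attribute = stage_attribute(config),
             account = stage_account(config),
             report = stage_report(config)),
      error = function(e)
        stop("stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    message(sprintf("stage %s done (%.1f s)", stage,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
  invisible(outdir)
}

stage_simulate <- function(config) {
  out <- config$outdir
  L <- config$landscape
  if (config$mode == "raster") {
    if (is.null(config$landscape_dir))
      stop("raster mode needs config$landscape_dir")
    ls <- read_landscape(config$landscape_dir)
    write_landscape(ls, file.path(out, "landscape"))
    return(invisible(NULL))
  }
  seed <- stage_seed(config, "simulate")
  n_cells_total <- prod(L$n_cells)
  beta1_cells <- NULL
  if (isTRUE(L$beta1_from_covariates) && n_cells_total >= 30) {
    covs <- simulate_cell_covariates(n_cells_total, seed = seed)
    tr <- generate_attribution_truth(
      n_cells_total,
      effects = list(mat = function(v) L$beta1 / 2 + v,
                     agriculture = function(v) 0.3 * v,
                     map = function(v) 0.006 * v),
      noise_sd = L$attribution_noise_sd, seed = seed, covariates = covs)
    beta1_cells <- tr$beta1_true
    covs$beta1_true <- tr$beta1_true
    write_table(covs, out, "covariates")
  } else {
    covs <- simulate_cell_covariates(n_cells_total, seed = seed)
    covs$beta1_true <- L$beta1
    write_table(covs, out, "covariates")
  }
  truth <- landscape_truth(beta0 = L$beta0, beta1 = L$beta1,
                           depth_star = L$depth_star,
                           noise_sd_white = L$noise_sd_white,
                           noise_sd_spatial = L$noise_sd_spatial,
                           noise_range_spatial = L$noise_range_spatial,
                           seed = seed + 1L)
  syn <- synthetic_landscape(
    n_cells = L$n_cells, cell_px = L$cell_px, resolution = L$resolution,
    truth = truth, beta1_cells = beta1_cells,
    clearings_per_cell = L$clearings_per_cell,
    clearing_px = L$clearing_px, seed = seed)
  write_landscape(syn$landscape, file.path(out, "landscape"))
  write_table(syn$cells, out, "cells")
  invisible(NULL)
}

stage_sample <- function(config) {
  out <- config$outdir
  ls <- read_landscape(file.path(out, "landscape"))
  cells <- if (config$mode == "raster")
    make_grid_cells(ls, config$landscape$cell_px) else
      read_table(out, "cells")
  if (config$mode == "raster") write_table(cells, out, "cells")
  pts <- sample_points(ls, cells,
                       n_per_cell = config$sampling$n_per_cell,
                       seed = stage_seed(config, "sample"))
  write_table(pts, out, "points")
  invisible(NULL)
}

stage_fit <- function(config) {
  out <- config$outdir
  pts <- read_table(out, "points")
  R <- config$regression
  Fl <- config$filters
  flt <- filter_cells(pts, min_points = Fl$min_points,
                      near_frac = Fl$near_frac, near_dist = Fl$near_dist,
                      exclude_within = Fl$exclude_within)
  write_table(flt$cells, out, "cell_filter_ledger")
  est <- fit_cells(flt$points, response = R$response, k = R$k,
                   alpha = R$alpha, nperm = R$nperm,
                   max_vectors = R$max_vectors,
                   seed = stage_seed(config, "fit"))
  est <- trim_outliers(est, R$tail_fraction)
  est$effect_class <- as.character(classify_effect(est$beta1))
  cells <- read_table(out, "cells")
  bio <- assign_biomes(cells, config$biomes$labels)
  est <- merge(est, bio, by = "cell_id", sort = TRUE)
  write_table(est, out, "estimates")
  summ <- rbind(weighted_summary(est),
                weighted_summary(est, group = est$biome))
  write_table(summ, out, "effect_summaries")
  invisible(NULL)
}

stage_attribute <- function(config) {
  out <- config$outdir
  est <- read_table(out, "estimates")
  covs <- read_table(out, "covariates")
  dat <- merge(est, covs, by = "cell_id", sort = TRUE)
  feat_names <- c("mat", "map", "wind", "soil_moisture", "elevation",
                  "slope", "agriculture")
  ok <- is.finite(dat$cv) & dat$cv > 0
  dat <- dat[ok, , drop = FALSE]
  sc <- collinearity_screen(dat[, feat_names])
  fit <- fit_attribution_model(dat[, sc$retained, drop = FALSE],
                               dat$beta1, weights = 1 / dat$cv,
                               tuning_budget = config$attribution$tuning_budget,
                               seed = stage_seed(config, "attribute"))
  sh <- shap_summary(fit, dat[, sc$retained, drop = FALSE])
  metrics <- list(holdout = as.list(fit$metrics),
                  params = fit$params, nrounds = fit$nrounds,
                  retained_features = sc$retained,
                  dropped_features = sc$dropped,
                  mean_abs_shap = as.list(sh$mean_abs),
                  shap_additivity_max_err = sh$additivity_max_err,
                  seed = stage_seed(config, "attribute"))
  if (isTRUE(config$attribution$run_buffered_cv)) {
    metrics$buffered_cv <- lapply(config$attribution$buffer_radii,
      function(r) {
        cv <- spatial_buffered_loo(dat[, sc$retained, drop = FALSE],
                                   dat$beta1, cbind(dat$x, dat$y),
                                   buffer = r, weights = 1 / dat$cv,
                                   seed = stage_seed(config, "attribute"))
        list(buffer = r, r2 = cv$r2, n_skipped = cv$n_skipped)
      })
  }
  jsonlite::write_json(metrics, file.path(out, "attribution_metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  shap_tab <- cbind(cell_id = dat$cell_id, as.data.frame(sh$shap))
  write_table(shap_tab, out, "shap_values")
  write_table(data.frame(feature = names(sh$mean_abs),
                         mean_abs_shap = as.numeric(sh$mean_abs)),
              out, "shap_importance")
  invisible(NULL)
}

stage_account <- function(config) {
  out <- config$outdir
  ls <- read_landscape(file.path(out, "landscape"))
  cells <- read_table(out, "cells")
  est <- read_table(out, "estimates")
  pts <- read_table(out, "points")
  A <- config$accounting
  acc <- account_cells(ls, cells, est, pts, percentile = A$percentile,
                       mode = A$mode, min_points = A$min_points)
  acc <- merge(acc, est[, c("cell_id", "biome")], by = "cell_id")
  write_table(acc, out, "accounts")
  totals <- aggregate_missing(acc, biome = acc$biome)
  totals$carbon_pg <- biomass_to_carbon(pmax(0, totals$missing_pg))
  write_table(totals, out, "missing_biomass_totals")
  invisible(NULL)
}

stage_report <- function(config) {
  out <- config$outdir
  est <- read_table(out, "estimates")
  summ <- read_table(out, "effect_summaries")
  totals <- read_table(out, "missing_biomass_totals")
  class_tab <- as.data.frame(table(effect_class = est$effect_class))
  write_table(class_tab, out, "effect_class_counts")
  grDevices::pdf(file.path(out, "report.pdf"), width = 8, height = 6)
  on.exit(grDevices::dev.off())
  graphics::hist(est$beta1, breaks = 30,
                 main = "Edge effect across cells",
                 xlab = "dAGB/dD (Mg/ha per log10 m)")
  bs <- summ[summ$group != "global", ]
  mid <- graphics::barplot(bs$mean_beta1, names.arg = bs$group,
                           ylab = "weighted mean dAGB/dD",
                           ylim = range(0, bs$mean_beta1 + bs$sd_beta1),
                           main = "Edge effect by biome (inverse-CV weighted)")
  graphics::arrows(mid, bs$mean_beta1 - bs$sd_beta1, mid,
                   bs$mean_beta1 + bs$sd_beta1, angle = 90, code = 3,
                   length = 0.05)
  tb <- totals[totals$group != "global", ]
  graphics::barplot(tb$missing_pg, names.arg = tb$group,
                    ylab = "missing AGB (Pg)",
                    main = "Missing biomass by biome")
  invisible(NULL)
}
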