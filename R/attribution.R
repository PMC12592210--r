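#' Collinearity screen for attribution covariates
#'
#' Reports all pairwise Spearman rank correlations and variance inflation
#' factors, then prunes: constant covariates are dropped first (undefined
#' correlation, with a warning); while any pair has `|rho| >= rho_max`, the
#' member of the worst pair with the larger mean `|rho|` against the
#' remaining covariates is dropped; finally, while any VIF `>= vif_max`,
#' the covariate with the largest VIF is dropped. The rules are
#' deterministic, so screening the retained set again changes nothing.
#'
#' @param covariates Data frame of numeric covariates (features only).
#' @param rho_max Spearman threshold (default 0.7).
#' @param vif_max VIF threshold (default 3).
#' @return List with `retained` (names), `dropped` (data frame
#'   `name`/`reason`), `spearman` (correlation matrix of the input),
#'   `vif` (named VIFs of the retained set).
#' @export
collinearity_screen <- function(covariates, rho_max = 0.7, vif_max = 3) {
  stopifnot(ncol(covariates) >= 2, nrow(covariates) >= 10)
  covariates <- as.data.frame(covariates)
  dropped <- data.frame(name = character(0), reason = character(0))
  const <- names(covariates)[vapply(covariates, function(v)
    stats::sd(v) == 0, logical(1))]
  if (length(const) > 0) {
    warning("constant covariate(s) dropped: ",
            paste(const, collapse = ", "))
    dropped <- rbind(dropped, data.frame(name = const, reason = "constant"))
    covariates <- covariates[, setdiff(names(covariates), const),
                             drop = FALSE]
  }
  S_full <- stats::cor(covariates, method = "spearman")
  keep <- names(covariates)
  repeat {
    if (length(keep) < 2) break
    S <- abs(stats::cor(covariates[keep], method = "spearman"))
    diag(S) <- 0
    if (max(S) < rho_max) break
    worst <- which(S == max(S), arr.ind = TRUE)[1, ]
    pair <- keep[worst]
    # drop the member more entangled with everything else
    mean_rho <- vapply(pair, function(nm)
      mean(S[nm, setdiff(keep, nm)]), numeric(1))
    out <- pair[which.max(mean_rho)]
    dropped <- rbind(dropped,
                     data.frame(name = out, reason = "spearman"))
    keep <- setdiff(keep, out)
  }
  vif <- function(vars) {
    vapply(vars, function(nm) {
      r2 <- summary(stats::lm(
        stats::reformulate(setdiff(vars, nm), response = nm),
        data = covariates))$r.squared
      1 / (1 - min(r2, 1 - 1e-12))
    }, numeric(1))
  }
  repeat {
    if (length(keep) < 2) break
    v <- vif(keep)
    if (max(v) < vif_max) break
    out <- keep[which.max(v)]
    dropped <- rbind(dropped, data.frame(name = out, reason = "vif"))
    keep <- setdiff(keep, out)
  }
  list(retained = keep, dropped = dropped, spearman = S_full,
       vif = if (length(keep) >= 2) vif(keep) else
         stats::setNames(rep(1, length(keep)), keep))
}

#' Deterministic default XGBoost parameters
#'
#' Conservative single-threaded exact-greedy settings with no row or
#' column subsampling, used where reproducibility across folds matters
#' (e.g. [spatial_buffered_loo()]).
#'
#' @return Named parameter list for [xgboost::xgb.train()].
#' @export
default_xgb_params <- function() {
  list(max_depth = 4, eta = 0.1, subsample = 1, colsample_bytree = 1,
       min_child_weight = 2, lambda = 1, objective = "reg:squarederror",
       tree_method = "exact", nthread = 1)
}

xgb_metrics <- function(pred, obs) {
  c(rmse = sqrt(mean((pred - obs)^2)),
    r2 = 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2),
    mae = mean(abs(pred - obs)))
}

#' Gradient-boosted attribution model for edge-effect slopes
#'
#' Fits an XGBoost regression of the per-cell slope on the screened
#' environmental covariates. 80% of the data (seeded split) trains the
#' model, with each training point weighted by the inverse coefficient of
#' variation of its slope estimate; hyperparameters are tuned within a
#' fixed budget by seeded Latin-hypercube random search over tree depth,
#' learning rate, subsampling rates, minimum child weight and L2
#' regularisation, scored on an inner validation split with early stopping.
#' RMSE, R-squared (`1 - SSE/SST`) and MAE are reported on the held-out
#' 20%.
#'
#' @param features Data frame of screened covariates (one row per cell).
#' @param target Numeric vector of slopes (`beta1`).
#' @param weights Positive training weights (default all 1; typically
#'   `1 / cv`).
#' @param tuning_budget Number of hyperparameter candidates (default 20;
#'   0 skips tuning and uses defaults).
#' @param test_frac Held-out fraction (default 0.2).
#' @param nrounds_max Boosting-round ceiling under early stopping.
#' @param seed Integer seed (split, search and xgboost RNG).
#' @return Object of class `"edge_xgb"`: `model`, `params`, `nrounds`,
#'   `metrics` (held-out rmse/r2/mae), `features` (column names),
#'   `test_idx`, `trace` (tuning table).
#' @export
fit_attribution_model <- function(features, target, weights = NULL,
                                  tuning_budget = 20, test_frac = 0.2,
                                  nrounds_max = 400, seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 25) stop("need at least 25 cells for a train/test split")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights <= 0 | !is.finite(weights)))
    stop("weights must be positive and finite")
  set.seed(seed)
  test_idx <- sort(sample.int(n, max(1, round(test_frac * n))))
  tr <- setdiff(seq_len(n), test_idx)
  val <- sort(sample(tr, max(1, round(0.25 * length(tr)))))
  tr_in <- setdiff(tr, val)

  space <- function(u) {
    list(max_depth = as.integer(2 + floor(u[1] * 7)),       # 2..8
         eta = 10^(-2 + 1.5 * u[2]),                        # 0.01..0.32
         subsample = 0.5 + 0.5 * u[3],
         colsample_bytree = 0.5 + 0.5 * u[4],
         min_child_weight = 1 + 9 * u[5],
         lambda = 10^(-1 + 2 * u[6]))
  }
  train_one <- function(par, data_idx, watch_idx, rounds, early) {
    dtr <- xgboost::xgb.DMatrix(X[data_idx, , drop = FALSE],
                                label = target[data_idx],
                                weight = weights[data_idx])
    par <- c(par, list(objective = "reg:squarederror",
                       tree_method = "exact", nthread = 1,
                       seed = seed))
    if (!is.null(watch_idx)) {
      dva <- xgboost::xgb.DMatrix(X[watch_idx, , drop = FALSE],
                                  label = target[watch_idx],
                                  weight = weights[watch_idx])
      xgboost::xgb.train(par, dtr, nrounds = rounds,
                         evals = list(val = dva),
                         early_stopping_rounds = early, verbose = 0)
    } else {
      xgboost::xgb.train(par, dtr, nrounds = rounds, verbose = 0)
    }
  }
  best_par <- default_xgb_params()[
    c("max_depth", "eta", "subsample", "colsample_bytree",
      "min_child_weight", "lambda")]
  best_rounds <- 150
  trace <- NULL
  if (tuning_budget > 0) {
    set.seed(seed)
    U <- lhs::randomLHS(tuning_budget, 6)
    cands <- apply(U, 1, space, simplify = FALSE)
    evals <- lapply(cands, function(par) {
      m <- train_one(par, tr_in, val, nrounds_max, 20)
      at <- xgboost::xgb.attributes(m)
      c(score = as.numeric(at$best_score),
        rounds = as.numeric(at$best_iteration))
    })
    scores <- vapply(evals, `[[`, numeric(1), "score")
    rounds <- vapply(evals, `[[`, numeric(1), "rounds")
    trace <- cbind(do.call(rbind, lapply(cands, as.data.frame)),
                   val_rmse = scores, best_iteration = rounds)
    best <- which.min(scores)
    best_par <- cands[[best]]
    best_rounds <- max(1, rounds[best])
  }
  model <- train_one(best_par, tr, NULL, best_rounds, NULL)
  pred <- predict(model, X[test_idx, , drop = FALSE])
  structure(list(model = model, params = best_par, nrounds = best_rounds,
                 metrics = xgb_metrics(pred, target[test_idx]),
                 features = colnames(X), test_idx = test_idx,
                 trace = trace, seed = seed),
            class = "edge_xgb")
}

#' @export
print.edge_xgb <- function(x, ...) {
  cat("Edge-effect attribution model (xgboost,", x$nrounds, "rounds)\n")
  cat(sprintf("  held-out: RMSE %.3f, R2 %.3f, MAE %.3f (n_test = %d)\n",
              x$metrics["rmse"], x$metrics["r2"], x$metrics["mae"],
              length(x$test_idx)))
  cat("  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' @export
predict.edge_xgb <- function(object, newdata, ...) {
  X <- as.matrix(newdata[, object$features, drop = FALSE])
  predict(object$model, X)
}

#' Spatially buffered leave-one-out cross-validation
#'
#' For each cell, an XGBoost model is trained on all cells farther than
#' `buffer` from it (the held-out cell itself always excluded) and used to
#' predict the held-out slope; the pooled predictions give one R-squared
#' (`1 - SSE/SST`). Folds whose exclusion zone leaves no training data are
#' skipped and counted; if every fold is skipped, an error is raised. With
#' `buffer = 0` this is plain leave-one-out.
#'
#' @param features Data frame of covariates.
#' @param target Numeric slopes.
#' @param coords Two-column matrix of cell coordinates (same distance
#'   units as `buffer`).
#' @param buffer Exclusion radius around the held-out cell.
#' @param weights Optional positive training weights.
#' @param params XGBoost parameter list (default [default_xgb_params()],
#'   deterministic).
#' @param nrounds Boosting rounds per fold (default 150).
#' @param seed Integer seed (xgboost RNG).
#' @return List with `r2`, `predictions` (`NA` for skipped folds),
#'   `n_folds`, `n_skipped`, `buffer`.
#' @export
spatial_buffered_loo <- function(features, target, coords, buffer = 0,
                                 weights = NULL, params = NULL,
                                 nrounds = 150, seed = 1L) {
  X <- as.matrix(features)
  n <- nrow(X)
  coords <- as.matrix(coords)
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(params)) params <- default_xgb_params()
  params$seed <- seed
  dm <- as.matrix(stats::dist(coords))
  pred <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    tr <- which(dm[i, ] > buffer)
    tr <- setdiff(tr, i)
    if (length(tr) == 0) {
      skipped <- skipped + 1L
      next
    }
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE],
                                label = target[tr], weight = weights[tr])
    m <- xgboost::xgb.train(params, dtr, nrounds = nrounds, verbose = 0)
    pred[i] <- predict(m, X[i, , drop = FALSE])
  }
  if (skipped == n)
    stop("buffer too large: no fold has any training data")
  ok <- !is.na(pred)
  r2 <- 1 - sum((target[ok] - pred[ok])^2) /
    sum((target[ok] - mean(target[ok]))^2)
  list(r2 = r2, predictions = pred, n_folds = n, n_skipped = skipped,
       buffer = buffer)
}

#' SHAP decomposition of the attribution model
#'
#' Exact TreeSHAP values per cell and covariate, the base value, and the
#' mean |SHAP| importance ranking. Additivity (base value plus the SHAP
#' values of all covariates equals the model prediction) is verified and
#' the maximum discrepancy reported.
#'
#' @param fit An `"edge_xgb"` model.
#' @param features Data frame containing the model's feature columns.
#' @return Object of class `"edge_shap"`: `shap` (n x p matrix),
#'   `base_value`, `mean_abs` (named, sorted decreasing), `prediction`,
#'   `additivity_max_err`, `values` (the feature values, for dependence
#'   plots).
#' @export
shap_summary <- function(fit, features) {
  stopifnot(inherits(fit, "edge_xgb"))
  if (!all(fit$features %in% names(features)))
    stop("feature set mismatch: model needs ",
         paste(setdiff(fit$features, names(features)), collapse = ", "))
  X <- as.matrix(features[, fit$features, drop = FALSE])
  contrib <- predict(fit$model, X, predcontrib = TRUE)
  bias_col <- ncol(contrib)
  shap <- contrib[, -bias_col, drop = FALSE]
  colnames(shap) <- fit$features
  pred <- predict(fit$model, X)
  err <- max(abs(rowSums(contrib) - pred))
  mean_abs <- sort(colMeans(abs(shap)), decreasing = TRUE)
  structure(list(shap = shap, base_value = mean(contrib[, bias_col]),
                 mean_abs = mean_abs, prediction = pred,
                 additivity_max_err = err, values = X),
            class = "edge_shap")
}

#' @export
print.edge_shap <- function(x, ...) {
  cat("SHAP summary (base value", round(x$base_value, 3), ")\n")
  cat("  mean |SHAP| ranking:\n")
  for (nm in names(x$mean_abs))
    cat(sprintf("    %-14s %.3f\n", nm, x$mean_abs[[nm]]))
  invisible(x)
}

#' @export
plot.edge_shap <- function(x, ...) {
  graphics::barplot(rev(x$mean_abs), horiz = TRUE, las = 1,
                    xlab = "mean |SHAP| (Mg/ha per log10 m)", ...)
  invisible(x)
}

#' Dependence-plot table for one covariate
#'
#' @param shap An `"edge_shap"` object.
#' @param feature Covariate to tabulate.
#' @param colour_by Optional second covariate used as an interaction
#'   colouring column.
#' @return Data frame with `value`, `shap` and optionally `colour`.
#' @export
shap_dependence <- function(shap, feature, colour_by = NULL) {
  stopifnot(feature %in% colnames(shap$shap))
  out <- data.frame(value = shap$values[, feature],
                    shap = shap$shap[, feature])
  if (!is.null(colour_by)) out$colour <- shap$values[, colour_by]
  out
}

#' Biome-level attribution models
#'
#' Runs the screen + weighted fit + SHAP chain separately per biome. Cells
#' flagged as straddling more than one biome are excluded throughout;
#' biomes with fewer than 25 remaining cells are skipped with a warning.
#'
#' @param features Covariate data frame (one row per cell).
#' @param target Numeric slopes.
#' @param biome Character/factor biome label per cell.
#' @param straddling Logical flag per cell (`TRUE` = spans several biomes).
#' @param weights Optional training weights.
#' @param ... Passed to [fit_attribution_model()].
#' @return Named list (one element per fitted biome) of lists with
#'   `screen`, `fit`, `shap`, `n_cells`.
#' @export
biome_models <- function(features, target, biome,
                         straddling = rep(FALSE, length(target)),
                         weights = NULL, ...) {
  keep <- !straddling
  out <- list()
  for (b in unique(as.character(biome[keep]))) {
    idx <- which(keep & as.character(biome) == b)
    if (length(idx) < 25) {
      warning("biome ", b, " skipped: only ", length(idx), " cells")
      next
    }
    sc <- collinearity_screen(features[idx, , drop = FALSE])
    ft <- fit_attribution_model(
      features[idx, sc$retained, drop = FALSE], target[idx],
      weights = if (is.null(weights)) NULL else weights[idx], ...)
    out[[b]] <- list(screen = sc,
                     fit = ft,
                     shap = shap_summary(ft, features[idx, , drop = FALSE]),
                     n_cells = length(idx))
  }
  out
}
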