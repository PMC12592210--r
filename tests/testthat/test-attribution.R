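feature_cols <- c("mat", "map", "wind", "soil_moisture", "elevation",
                  "slope", "agriculture")

test_that("collinearity screen drops duplicates and keeps independents", {
  covs <- simulate_cell_covariates(150, seed = 1)[, feature_cols]
  # independent uniforms: everything retained
  sc <- collinearity_screen(covs)
  expect_setequal(sc$retained, feature_cols)
  expect_true(all(sc$vif < 3))
  # a duplicated covariate: exactly one of the pair goes
  covs2 <- covs
  covs2$mat2 <- covs2$mat
  sc2 <- collinearity_screen(covs2)
  expect_equal(sum(c("mat", "mat2") %in% sc2$retained), 1)
  expect_equal(nrow(sc2$dropped), 1)
  # screening is idempotent
  sc3 <- collinearity_screen(covs2[, sc2$retained])
  expect_setequal(sc3$retained, sc2$retained)
})

test_that("orthogonal designs have unit VIFs and constants are dropped", {
  des <- expand.grid(a = c(-1, 1), b = c(-1, 1), c = c(-1, 1),
                     d = c(-1, 1))
  sc <- collinearity_screen(des)
  expect_equal(unname(sc$vif), rep(1, 4))
  des$e <- 7
  expect_warning(sc2 <- collinearity_screen(des), "constant")
  expect_false("e" %in% sc2$retained)
})

test_that("the attribution model recovers planted signal and not noise", {
  covs <- simulate_cell_covariates(200, seed = 2)[, feature_cols]
  target <- 2 * covs$mat
  fit <- fit_attribution_model(covs, target, tuning_budget = 8, seed = 2)
  expect_gt(fit$metrics["r2"], 0.95)
  # permuted target: no information
  set.seed(3)
  fit0 <- fit_attribution_model(covs, sample(target), tuning_budget = 8,
                                seed = 2)
  expect_lte(fit0$metrics["r2"], 0.1)
  # determinism under the seed
  fit2 <- fit_attribution_model(covs, target, tuning_budget = 8, seed = 2)
  expect_identical(fit$metrics, fit2$metrics)
  expect_identical(fit$params, fit2$params)
  expect_error(fit_attribution_model(covs[1:20, ], target[1:20]),
               "at least 25")
  expect_error(fit_attribution_model(covs, target, weights = rep(-1, 200)),
               "positive")
})

test_that("duplicating a cell equals doubling its training weight", {
  covs <- simulate_cell_covariates(20, seed = 4)
  feats <- covs[, c("mat", "map", "agriculture")]
  set.seed(4)
  y <- 0.5 * covs$mat + rnorm(20, sd = 1)
  dup <- c(seq_len(20), 2)           # cell 2 twice, unit weights
  cv_dup <- spatial_buffered_loo(feats[dup, ], y[dup],
                                 cbind(covs$x, covs$y)[dup, ],
                                 buffer = 0, weights = rep(1, 21),
                                 nrounds = 40, seed = 4)
  w <- rep(1, 20); w[2] <- 2         # cell 2 once, doubled weight
  cv_w <- spatial_buffered_loo(feats, y, cbind(covs$x, covs$y),
                               buffer = 0, weights = w, nrounds = 40,
                               seed = 4)
  expect_equal(cv_dup$predictions[1], cv_w$predictions[1], tolerance = 1e-7)
})

test_that("buffer = 0 spatial CV equals plain leave-one-out", {
  covs <- simulate_cell_covariates(30, seed = 5)
  feats <- covs[, c("mat", "map", "agriculture")]
  set.seed(5)
  y <- 0.01 * covs$map + rnorm(30, sd = 2)
  cv0 <- spatial_buffered_loo(feats, y, cbind(covs$x, covs$y), buffer = 0,
                              nrounds = 40, seed = 5)
  # independent plain-LOO oracle
  pr <- vapply(seq_len(30), function(i) {
    p <- default_xgb_params()
    p$seed <- 5
    m <- xgboost::xgb.train(
      p, xgboost::xgb.DMatrix(as.matrix(feats[-i, ]), label = y[-i]),
      nrounds = 40, verbose = 0)
    predict(m, as.matrix(feats[i, , drop = FALSE]))
  }, numeric(1))
  expect_equal(cv0$predictions, pr, tolerance = 1e-10)
  expect_equal(cv0$n_skipped, 0)
  # buffer spanning the whole domain: every fold empty
  expect_error(
    spatial_buffered_loo(feats, y, cbind(covs$x, covs$y), buffer = 1e6,
                         nrounds = 10, seed = 5),
    "buffer too large")
})

test_that("spatial leakage inflates R2 only at small buffers", {
  covs <- simulate_cell_covariates(80, seed = 6)
  set.seed(6)
  y <- 3 * covs$x + 3 * covs$y + rnorm(80, sd = 0.5)  # smooth confounder
  feats <- cbind(covs[, c("mat", "map", "wind")], x = covs$x, y = covs$y)
  r2 <- vapply(c(0, 2, 5), function(b)
    spatial_buffered_loo(feats, y, cbind(covs$x, covs$y), buffer = b,
                         nrounds = 50, seed = 6)$r2, numeric(1))
  expect_true(all(diff(r2) <= 0))
})

test_that("SHAP values are additive and rank the planted driver first", {
  tr <- generate_attribution_truth(
    150, effects = list(agriculture = function(v) 0.6 * v,
                        mat = function(v) 0.3 * v),
    noise_sd = 3, seed = 7)
  feats <- tr$covariates[, feature_cols]
  fit <- fit_attribution_model(feats, tr$beta1_true, tuning_budget = 8,
                               seed = 7)
  sh <- shap_summary(fit, feats)
  # single-precision tree sums: machine tolerance is ~1e-5 relative
  scale <- max(1, max(abs(sh$prediction)))
  expect_lt(sh$additivity_max_err / scale, 1e-5)
  expect_equal(names(sh$mean_abs)[1], "agriculture")
  dep <- shap_dependence(sh, "agriculture", colour_by = "mat")
  expect_named(dep, c("value", "shap", "colour"))
  expect_equal(nrow(dep), 150)
  expect_error(shap_summary(fit, feats[, 1:3]), "mismatch")
})

test_that("a constant covariate receives zero SHAP contribution", {
  covs <- simulate_cell_covariates(100, seed = 8)
  feats <- covs[, c("mat", "map")]
  feats$flat <- 1
  set.seed(8)
  y <- covs$mat + rnorm(100, sd = 0.5)
  fit <- fit_attribution_model(feats, y, tuning_budget = 0, seed = 8)
  sh <- shap_summary(fit, feats)
  expect_lt(max(abs(sh$shap[, "flat"])), 1e-8)
})

test_that("biome models exclude straddlers and find biome-specific drivers", {
  n <- 120
  covs <- simulate_cell_covariates(n, seed = 9)
  biome <- rep(c("tropical", "boreal"), each = n / 2)
  set.seed(9)
  y <- ifelse(biome == "tropical", 0.04 * covs$map, 3 * covs$mat) +
    rnorm(n, sd = 2)
  straddle <- rep(FALSE, n)
  straddle[c(1, 61)] <- TRUE
  fits <- suppressWarnings(
    biome_models(covs[, feature_cols], y, biome, straddling = straddle,
                 tuning_budget = 4, seed = 9))
  expect_setequal(names(fits), c("tropical", "boreal"))
  expect_equal(fits$tropical$n_cells, 59)
  expect_equal(fits$boreal$n_cells, 59)
  expect_equal(names(fits$tropical$shap$mean_abs)[1], "map")
  expect_equal(names(fits$boreal$shap$mean_abs)[1], "mat")
  # a biome below the size floor is skipped with a warning
  expect_warning(
    small <- biome_models(covs[1:40, feature_cols], y[1:40],
                          rep(c("a", "b"), c(30, 10)), tuning_budget = 2,
                          seed = 9),
    "skipped")
  expect_named(small, "a")
})

test_that("a single-biome model reproduces the global model", {
  covs <- simulate_cell_covariates(80, seed = 10)
  set.seed(10)
  y <- 0.2 * covs$agriculture + rnorm(80, sd = 1)
  fits <- biome_models(covs[, feature_cols], y, rep("all", 80),
                       tuning_budget = 4, seed = 11)
  sc <- collinearity_screen(covs[, feature_cols])
  glob <- fit_attribution_model(covs[, sc$retained], y, tuning_budget = 4,
                                seed = 11)
  expect_identical(fits$all$fit$metrics, glob$metrics)
})
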