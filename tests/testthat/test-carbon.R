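test_that("depth of edge influence finds the plateau onset region", {
  pts <- plateau_points(n = 800, depth_star = 200, d_max = 360)
  ds <- depth_of_edge_influence(pts)
  # noiseless plateau: the top decile sits on the plateau
  expect_gte(ds, 150)
  expect_lte(ds, 300)
  expect_identical(attr(ds, "mode"), "top")
  # band mode qualifies a band around the percentile instead
  dsb <- depth_of_edge_influence(pts, mode = "band", band = 0.05)
  expect_identical(attr(dsb, "mode"), "band")
  expect_true(is.finite(dsb))
})

test_that("flat biomass makes the depth distance-uninformative", {
  pts <- plateau_points(n = 300)
  pts$agb_mg_ha <- 77           # beta1 = 0, noiseless: all points qualify
  ds <- depth_of_edge_influence(pts)
  expect_equal(as.numeric(ds), mean(pts$distance_m))
  expect_equal(attr(ds, "n_qualifying"), 300)
})

test_that("too few qualifying points is an error", {
  # strictly monotone biomass: the top decile of 40 points is 4 points
  pts <- plateau_points(n = 40, depth_star = 1e6, d_max = 300)
  expect_error(depth_of_edge_influence(pts, min_points = 5), "qualifying")
  expect_silent(depth_of_edge_influence(pts, min_points = 4))
})

test_that("the counterfactual account matches hand arithmetic", {
  est <- list(beta0 = 100, beta1 = 50, se_beta1 = 0)
  obs <- 100 + 50 * log10(30)
  acc <- counterfactual_cell(obs, 30, est, d_star = 100, resolution = 30)
  expect_equal(acc$missing_mg, (200 - obs) * 0.09, tolerance = 1e-12)
  expect_equal(acc$edge_pixels, 1)
  expect_equal(acc$counterfactual_mg, acc$actual_mg + acc$missing_mg)
})

test_that("beta1 = 0 noiseless landscapes have exactly zero missing biomass", {
  b <- rep(80, 50)
  d <- seq(30, 1500, length.out = 50)
  est <- list(beta0 = 80, beta1 = 0, se_beta1 = 0)
  acc <- counterfactual_cell(b, d, est, d_star = 300, resolution = 30)
  expect_identical(acc$missing_mg, 0)
  expect_identical(acc$lower_mg, 0)
})

test_that("edge membership is strict and replacement conserves stock", {
  set.seed(1)
  d <- seq(30, 600, by = 30)
  b <- 50 + 45 * log10(d) + rnorm(length(d), sd = 5)
  est <- list(beta0 = 50, beta1 = 45, se_beta1 = 2)
  acc <- counterfactual_cell(b, d, est, d_star = 200, resolution = 30)
  # replaced set is exactly {pixels with D < 200}: D = 200 is interior
  expect_equal(acc$edge_pixels, sum(d < 200))
  repl <- 50 + 45 * log10(200)
  expect_equal(acc$missing_mg,
               sum((repl - b[d < 200]) * 0.09), tolerance = 1e-12)
  # CI ordering
  expect_lte(acc$lower_mg, acc$missing_mg)
  expect_gte(acc$upper_mg, acc$missing_mg)
  # monotonicity: a larger depth never shrinks the replaced set
  acc2 <- counterfactual_cell(b, d, est, d_star = 400, resolution = 30)
  expect_gte(acc2$edge_pixels, acc$edge_pixels)
  # depth below the resolution: nothing replaced
  expect_warning(
    acc3 <- counterfactual_cell(b, d, est, d_star = 10, resolution = 30),
    "resolution")
  expect_equal(acc3$missing_mg, 0)
})

test_that("negative replacement densities are clipped and counted", {
  est <- list(beta0 = 1, beta1 = -20, se_beta1 = 0)
  acc <- counterfactual_cell(c(5, 5), c(30, 60), est, d_star = 100,
                             resolution = 30)
  expect_equal(acc$clipped_pixels, 2)
  expect_equal(acc$counterfactual_mg, 0)
})

test_that("missing biomass on noiseless landscapes matches the analytic deficit", {
  ls <- generate_forest_mask(c(96, 96), seed = 3,
                             clearings = random_clearings(12, 12))
  tr <- landscape_truth(beta0 = 50, beta1 = 50, depth_star = 300,
                        noise_sd_white = 0, noise_sd_spatial = 0, seed = 4)
  lb <- generate_biomass(ls, tr)
  dd <- lb$distance[classify_forest(lb$cover, 30)]
  f <- function(x) 50 + 50 * log10(pmin(x, 300))
  analytic <- sum((f(300) - f(dd))[dd < 300]) * 0.09
  est <- list(beta0 = 50, beta1 = 50, se_beta1 = 0)
  acc <- counterfactual_cell(lb$biomass, lb$distance, est, d_star = 300,
                             resolution = 30)
  expect_equal(acc$missing_mg, analytic, tolerance = 0.01)
  expect_gte(acc$missing_mg, 0)
})

test_that("aggregation is additive with the printed percent formula", {
  acc <- data.frame(
    cell_id = 1:2,
    actual_mg = c(91e9, 60e9) / 2,
    counterfactual_mg = c(100e9 / 2, 100e9 / 2),
    missing_mg = c(9e9 / 2, 20e9 / 2),
    lower_mg = c(4e9 / 2, 15e9 / 2),
    upper_mg = c(14e9 / 2, 25e9 / 2))
  out <- aggregate_missing(acc, biome = c("tropical", "boreal"))
  glob <- out[out$group == "global", ]
  expect_equal(glob$missing_pg,
               sum(out$missing_pg[out$group != "global"]))
  expect_equal(out$percent[out$group == "tropical"], 9)  # 9 / 100 x 100
  expect_true(all(out$lower_pg <= out$missing_pg &
                    out$missing_pg <= out$upper_pg))
})

test_that("biomass-to-carbon follows the printed conversion chain", {
  expect_equal(biomass_to_carbon(58), 58 * 0.476)
  expect_equal(biomass_to_carbon(58, include_roots = TRUE),
               58 / 0.78 * 0.476)
  expect_equal(biomass_to_carbon(0), 0)
  expect_error(biomass_to_carbon(10, carbon_fraction = 1.2), "\\(0, 1\\)")
  expect_error(biomass_to_carbon(-1), ">= 0")
})
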