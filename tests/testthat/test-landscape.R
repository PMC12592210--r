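test_that("forest mask honours clearing specifications exactly", {
  ls <- generate_forest_mask(c(50, 50), clearings = no_clearings(), seed = 1)
  expect_equal(mean(classify_forest(ls$cover, 30)), 1)

  ls <- generate_forest_mask(
    c(100, 100),
    clearings = geometric_clearings(rbind(c(11, 11, 10, 10))), seed = 1)
  m <- classify_forest(ls$cover, 30)
  expect_equal(mean(m), 0.99)
  expect_false(any(m[11:20, 11:20]))
  expect_true(all(ls$cover >= 0 & ls$cover <= 100))
})

test_that("thresholded random fields realise the requested clearing fraction", {
  fracs <- vapply(1:20, function(s) {
    ls <- generate_forest_mask(c(60, 60),
                               clearings = field_clearings(0.3, range_px = 4),
                               seed = s)
    1 - mean(classify_forest(ls$cover, 30))
  }, numeric(1))
  expect_true(all(abs(fracs - 0.3) < 0.02))
  expect_lt(abs(mean(fracs) - 0.3), 0.005)
})

test_that("degenerate masks are rejected", {
  expect_error(generate_forest_mask(c(2, 10)), "degenerate")
  expect_error(
    generate_forest_mask(c(10, 10),
      clearings = geometric_clearings(rbind(c(1, 1, 10, 10)))),
    "no forest")
})

test_that("noiseless biomass follows the plateaued log-linear truth", {
  # flat field: beta1 = 0, zero noise
  ls <- generate_forest_mask(c(20, 20),
    clearings = geometric_clearings(rbind(c(1, 1, 1, 1))), seed = 2)
  tr <- landscape_truth(beta0 = 120, beta1 = 0, noise_sd_white = 0,
                        noise_sd_spatial = 0)
  lb <- generate_biomass(ls, tr)
  expect_true(all(lb$biomass[classify_forest(lb$cover, 30)] == 120))

  # exact value at D = 100 m: non-forest pixel 10 columns away, 10 m pixels
  ls <- generate_forest_mask(c(3, 15), resolution = 10,
    clearings = geometric_clearings(rbind(c(2, 1, 1, 1))), seed = 3)
  tr <- landscape_truth(beta0 = 100, beta1 = 50, depth_star = Inf,
                        noise_sd_white = 0, noise_sd_spatial = 0)
  lb <- generate_biomass(ls, tr)
  expect_equal(lb$distance[2, 11], 100)
  expect_equal(lb$biomass[2, 11], 100 + 50 * log10(100), tolerance = 1e-12)

  # plateau: value beyond depth_star equals the value at depth_star
  ls <- generate_forest_mask(c(3, 40), resolution = 30,
    clearings = geometric_clearings(rbind(c(1, 1, 3, 1))), seed = 4)
  tr <- landscape_truth(beta0 = 50, beta1 = 50, depth_star = 200,
                        noise_sd_white = 0, noise_sd_spatial = 0)
  lb <- generate_biomass(ls, tr)
  d <- lb$distance[2, ]
  far <- which(d >= 200)
  expect_gt(max(d, na.rm = TRUE), 900)
  expect_true(all(lb$biomass[2, far] == 50 + 50 * log10(200)))
})

test_that("negative biomass is clipped at zero and the count reported", {
  ls <- generate_forest_mask(c(30, 30),
    clearings = geometric_clearings(rbind(c(1, 1, 2, 2))), seed = 5)
  tr <- landscape_truth(beta0 = 5, beta1 = 0, noise_sd_white = 30,
                        noise_sd_spatial = 0, seed = 6)
  expect_message(lb <- generate_biomass(ls, tr), "clipped")
  expect_gt(lb$clipped_pixels, 0)
  expect_true(all(lb$biomass >= 0, na.rm = TRUE))
})

test_that("all-forest masks with an edge-dependent truth are rejected", {
  ls <- generate_forest_mask(c(10, 10), clearings = no_clearings(), seed = 1)
  expect_error(
    generate_biomass(ls, landscape_truth(beta1 = 10, depth_star = Inf)),
    "distance")
})

test_that("landscapes regenerate bit-identically under a fixed seed", {
  a <- synthetic_landscape(n_cells = c(2, 2), cell_px = 48,
                           truth = landscape_truth(seed = 9), seed = 8)
  b <- synthetic_landscape(n_cells = c(2, 2), cell_px = 48,
                           truth = landscape_truth(seed = 9), seed = 8)
  expect_identical(a$landscape$cover, b$landscape$cover)
  expect_identical(a$landscape$biomass, b$landscape$biomass)
  expect_identical(a$cells, b$cells)
})

test_that("noisy biomass is unbiased around the noiseless formula", {
  # one long edge, >= 1e4 pixels at the same fixed distance, iid noise
  n <- 10000
  ls <- generate_forest_mask(c(n, 5), resolution = 30,
    clearings = geometric_clearings(rbind(c(1, 1, n, 1))), seed = 10)
  tr <- landscape_truth(beta0 = 80, beta1 = 40, depth_star = Inf,
                        noise_sd_white = 15, noise_sd_spatial = 0,
                        seed = 11)
  lb <- generate_biomass(ls, tr)
  v <- lb$biomass[, 4]           # all at D = 90 m
  expect_equal(unique(lb$distance[, 4]), 90)
  mu <- 80 + 40 * log10(90)
  expect_lt(abs(mean(v) - mu), 3 * 15 / sqrt(n))
})

test_that("attribution truth plants recoverable covariate effects", {
  # single linear effect, zero noise: perfect rank correlation
  tr <- generate_attribution_truth(60, effects = list(mat = function(v) 3 * v),
                                   noise_sd = 0, seed = 1)
  expect_equal(cor(tr$covariates$mat, tr$beta1_true, method = "spearman"), 1)

  # all effects zero: variance of the truth equals the noise variance
  vars <- vapply(1:50, function(s) {
    t0 <- generate_attribution_truth(
      60, effects = list(mat = function(v) 0 * v), noise_sd = 5, seed = s)
    var(t0$beta1_true)
  }, numeric(1))
  se <- 25 * sqrt(2 / 59 / 50)
  expect_lt(abs(mean(vars) - 25), 4 * se)

  # determinism and unknown-covariate error
  a <- generate_attribution_truth(40, noise_sd = 2, seed = 3)
  b <- generate_attribution_truth(40, noise_sd = 2, seed = 3)
  expect_identical(a, b)
  expect_error(
    generate_attribution_truth(40, effects = list(nope = identity)),
    "unknown covariate")
  expect_error(generate_attribution_truth(10), ">= 30")
})
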