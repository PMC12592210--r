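#' Ground truth for a synthetic fragmented landscape
#'
#' Bundles the generative parameters of the biomass--distance-to-edge
#' relationship used by [generate_biomass()]: noiseless biomass density at a
#' forest pixel with distance-to-edge `D` (m) is
#' `beta0 + beta1 * log10(min(D, depth_star))`, i.e. a log-linear rise from
#' the edge that plateaus beyond the depth of edge influence `depth_star`.
#'
#' @param beta0 Biomass intercept (Mg ha^-1) at D = 1 m. Must be >= 0.
#' @param beta1 True slope of biomass on log10 distance
#'   (Mg ha^-1 per log10 m). Positive values mean lower biomass near edges.
#' @param depth_star Plateau distance (m); biomass stops increasing beyond
#'   it. May be `Inf` (pure log-linear gradient). Must be > 0.
#' @param noise_sd_white Standard deviation of white pixel noise (Mg ha^-1).
#' @param noise_sd_spatial Standard deviation of the spatially correlated
#'   noise component (Mg ha^-1).
#' @param noise_range_spatial Correlation range of the spatial noise (m);
#'   implemented as the sigma of a Gaussian smoothing kernel applied to a
#'   white-noise field.
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical landscapes.
#' @return An object of class `"landscape_truth"` (a validated list).
#' @seealso [generate_biomass()], [synthetic_landscape()]
#' @export
landscape_truth <- function(beta0 = 50, beta1 = 50, depth_star = 300,
                            noise_sd_white = 15, noise_sd_spatial = 8,
                            noise_range_spatial = 120, seed = 1L) {
  if (beta0 < 0) stop("beta0 must be >= 0")
  if (!(depth_star > 0)) stop("depth_star must be > 0")
  if (noise_sd_white < 0 || noise_sd_spatial < 0)
    stop("noise standard deviations must be >= 0")
  if (noise_range_spatial <= 0) stop("noise_range_spatial must be > 0")
  structure(list(beta0 = beta0, beta1 = beta1, depth_star = depth_star,
                 noise_sd_white = noise_sd_white,
                 noise_sd_spatial = noise_sd_spatial,
                 noise_range_spatial = noise_range_spatial,
                 seed = as.integer(seed)),
            class = "landscape_truth")
}

#' @export
print.landscape_truth <- function(x, ...) {
  cat("Landscape truth: AGB = ", x$beta0, " + ", x$beta1,
      " * log10(min(D, ", x$depth_star, " m))\n", sep = "")
  cat("  noise: white sd ", x$noise_sd_white, ", spatial sd ",
      x$noise_sd_spatial, " (range ", x$noise_range_spatial,
      " m), seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Clearing specifications for the forest-mask generator
#'
#' Three ways to carve non-forest out of an otherwise fully forested grid:
#' `geometric_clearings()` takes explicit rectangles (rows `row`, `col`,
#' `height`, `width` in pixels, 1-based top-left corners);
#' `random_clearings()` scatters `n` square clearings of side `size_px`
#' uniformly; `field_clearings()` thresholds a spatially correlated random
#' field at the `nonforest_frac` quantile, giving organic clearing shapes
#' whose realised non-forest fraction equals the requested quantile up to
#' ties. `no_clearings()` leaves the grid fully forested.
#'
#' @param rects Integer matrix with columns `row`, `col`, `height`, `width`.
#' @param n Number of square clearings.
#' @param size_px Side of each square clearing, in pixels.
#' @param nonforest_frac Target non-forest fraction in (0, 1).
#' @param range_px Correlation range (sigma, pixels) of the random field.
#' @return A clearing specification list consumed by
#'   [generate_forest_mask()].
#' @export
geometric_clearings <- function(rects) {
  rects <- as.matrix(rects)
  if (ncol(rects) != 4) stop("rects needs columns row, col, height, width")
  colnames(rects) <- c("row", "col", "height", "width")
  list(kind = "geometric", rects = rects)
}

#' @rdname geometric_clearings
#' @export
random_clearings <- function(n = 3, size_px = 12) {
  stopifnot(n >= 0, size_px >= 1)
  list(kind = "random", n = as.integer(n), size_px = as.integer(size_px))
}

#' @rdname geometric_clearings
#' @export
field_clearings <- function(nonforest_frac = 0.3, range_px = 8) {
  stopifnot(nonforest_frac > 0, nonforest_frac < 1, range_px > 0)
  list(kind = "field", nonforest_frac = nonforest_frac, range_px = range_px)
}

#' @rdname geometric_clearings
#' @export
no_clearings <- function() list(kind = "none")

# Separable Gaussian smoothing with circular (torus) boundary; used for
# correlated random fields so the field statistics are stationary.
gaussian_smooth <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  w <- min(ceiling(3 * sigma_px), floor((min(dim(m)) - 1) / 2))
  if (w < 1) return(m)
  k <- exp(-((-w):w)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  m1 <- apply(m, 2, function(col) stats::filter(col, k, circular = TRUE))
  m2 <- t(apply(m1, 1, function(row) stats::filter(row, k, circular = TRUE)))
  matrix(as.numeric(m2), nrow(m), ncol(m))
}

# Spatially correlated standard field: smoothed white noise rescaled to
# unit sd. Assumes RNG state already set by the caller.
correlated_field <- function(shape, range_px) {
  z <- matrix(stats::rnorm(prod(shape)), shape[1], shape[2])
  s <- gaussian_smooth(z, range_px)
  (s - mean(s)) / stats::sd(s)
}

#' Generate a fragmented forest-cover grid
#'
#' Builds a percent tree-cover grid in which "forest" pixels carry cover
#' drawn uniformly in `[threshold, 100]` and cleared pixels cover in
#' `[0, threshold)`; only the implied binary mask matters downstream.
#'
#' @param shape Grid dimensions `c(rows, cols)` in pixels; at least 3x3.
#' @param resolution Pixel side length in metres.
#' @param clearings A clearing specification, see [geometric_clearings()].
#' @param threshold Percent tree-cover threshold separating forest from
#'   non-forest (default 30, trees taller than 5 m assumed).
#' @param seed Integer seed.
#' @param origin Planar coordinates (m) of the grid's lower-left corner.
#' @return A `"forest_landscape"` object: list with `cover` (matrix,
#'   percent), `resolution`, `origin`, `threshold`.
#' @export
generate_forest_mask <- function(shape, resolution = 30,
                                 clearings = random_clearings(),
                                 threshold = 30, seed = 1L,
                                 origin = c(0, 0)) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 3))
    stop("degenerate shape: grid must be at least 3x3")
  if (resolution <= 0) stop("resolution must be > 0")
  set.seed(seed)
  nonforest <- matrix(FALSE, shape[1], shape[2])
  kind <- clearings$kind
  if (kind == "geometric") {
    r <- clearings$rects
    for (i in seq_len(nrow(r))) {
      rows <- r[i, "row"]:min(shape[1], r[i, "row"] + r[i, "height"] - 1)
      cols <- r[i, "col"]:min(shape[2], r[i, "col"] + r[i, "width"] - 1)
      nonforest[rows, cols] <- TRUE
    }
  } else if (kind == "random") {
    if (clearings$n > 0) {
      sz <- min(clearings$size_px, min(shape))
      r0 <- sample.int(shape[1] - sz + 1, clearings$n, replace = TRUE)
      c0 <- sample.int(shape[2] - sz + 1, clearings$n, replace = TRUE)
      for (i in seq_len(clearings$n))
        nonforest[r0[i]:(r0[i] + sz - 1), c0[i]:(c0[i] + sz - 1)] <- TRUE
    }
  } else if (kind == "field") {
    g <- correlated_field(shape, clearings$range_px)
    nonforest <- g <= stats::quantile(g, clearings$nonforest_frac)
  } else if (kind != "none") {
    stop("unknown clearing kind: ", kind)
  }
  if (all(nonforest)) stop("no forest: clearing covers the whole grid")
  cover <- matrix(stats::runif(prod(shape), threshold, 100),
                  shape[1], shape[2])
  n_nf <- sum(nonforest)
  if (n_nf > 0) cover[nonforest] <- stats::runif(n_nf, 0, threshold * 0.999)
  structure(list(cover = cover, biomass = NULL, distance = NULL,
                 resolution = resolution, origin = origin,
                 threshold = threshold, seed = as.integer(seed)),
            class = "forest_landscape")
}

#' @export
print.forest_landscape <- function(x, ...) {
  d <- dim(x$cover)
  cat("Forest landscape: ", d[1], " x ", d[2], " px at ", x$resolution,
      " m (", round(100 * mean(x$cover >= x$threshold), 1),
      "% forest at >=", x$threshold, "% cover)\n", sep = "")
  if (!is.null(x$biomass))
    cat("  biomass: mean ",
        round(mean(x$biomass, na.rm = TRUE), 1), " Mg/ha over forest, ",
        x$clipped_pixels, " pixel(s) clipped at 0\n", sep = "")
  invisible(x)
}

#' Generate a biomass layer over a forest mask
#'
#' Fills forest pixels with
#' `beta0 + beta1 * log10(min(D, depth_star)) + noise`, where `D` is the
#' Euclidean distance (m) to the nearest non-forest pixel. Noise is the sum
#' of white noise and a spatially correlated component (Gaussian-kernel
#' smoothed white noise scaled to the requested sd). Negative values are
#' clipped at zero and the number of clipped pixels is reported in the
#' returned object (`clipped_pixels`) and via a message.
#'
#' @param landscape A `"forest_landscape"` from [generate_forest_mask()].
#' @param truth A [landscape_truth()] object.
#' @param beta1_grid Optional matrix of per-pixel slopes (same shape as the
#'   cover grid) overriding `truth$beta1`, for landscapes whose edge effect
#'   varies between cells.
#' @return The landscape with `biomass` (Mg ha^-1, `NA` on non-forest),
#'   `distance` (m), `truth` and `clipped_pixels` filled in.
#' @export
generate_biomass <- function(landscape, truth = landscape_truth(),
                             beta1_grid = NULL) {
  stopifnot(inherits(landscape, "forest_landscape"),
            inherits(truth, "landscape_truth"))
  mask <- classify_forest(landscape$cover, landscape$threshold)
  D <- distance_to_edge(mask, landscape$resolution)
  b1 <- if (is.null(beta1_grid)) truth$beta1 else beta1_grid[mask]
  if (any(is.infinite(D[mask]))) {
    if (any(b1 != 0) && is.infinite(truth$depth_star))
      stop("all-forest mask: distance to edge undefined with beta1 != 0 ",
           "and infinite depth_star")
    D[is.infinite(D)] <- truth$depth_star
  }
  shape <- dim(mask)
  mu <- truth$beta0 + b1 * log10(pmin(D[mask], truth$depth_star))
  set.seed(truth$seed)
  noise <- stats::rnorm(sum(mask), sd = truth$noise_sd_white)
  if (truth$noise_sd_spatial > 0) {
    f <- correlated_field(shape, truth$noise_range_spatial /
                            landscape$resolution)
    noise <- noise + truth$noise_sd_spatial * f[mask]
  }
  b <- mu + noise
  clipped <- sum(b < 0)
  if (clipped > 0)
    message(clipped, " biomass pixel(s) clipped at 0")
  b[b < 0] <- 0
  biomass <- matrix(NA_real_, shape[1], shape[2])
  biomass[mask] <- b
  landscape$biomass <- biomass
  landscape$distance <- D
  landscape$truth <- truth
  landscape$clipped_pixels <- clipped
  landscape
}

#' Simulate a multi-cell fragmented landscape with known truth
#'
#' Convenience wrapper producing the full synthetic test substrate: a
#' forest mask tiled into analysis cells, a biomass layer following the
#' plateaued log-linear truth (optionally with a different slope per cell),
#' and the cell table from [make_grid_cells()].
#'
#' @param n_cells `c(rows, cols)` of analysis cells.
#' @param cell_px Cell side in pixels (default 96).
#' @param resolution Pixel size in metres (default 30).
#' @param truth A [landscape_truth()]; its `beta1` is used for every cell
#'   unless `beta1_cells` is given.
#' @param beta1_cells Optional vector of per-cell slopes, length
#'   `prod(n_cells)`, in cell order (row-major over the cell grid).
#' @param clearings_per_cell Number of random square clearings per cell
#'   (default 12, which at the default cell and clearing sizes puts roughly
#'   30% of forest pixels within 100 m of an edge, the fragmentation level
#'   reported for global forests).
#' @param clearing_px Side of each clearing in pixels.
#' @param seed Integer seed (mask placement; biomass noise uses
#'   `truth$seed`).
#' @return List with `landscape` (a `"forest_landscape"` with biomass),
#'   `cells` (data frame from [make_grid_cells()]) and `truth`.
#' @export
synthetic_landscape <- function(n_cells = c(4, 5), cell_px = 96,
                                resolution = 30,
                                truth = landscape_truth(),
                                beta1_cells = NULL,
                                clearings_per_cell = 12, clearing_px = 12,
                                seed = 1L) {
  shape <- as.integer(n_cells) * cell_px
  ls <- generate_forest_mask(
    shape, resolution = resolution,
    clearings = random_clearings(clearings_per_cell * prod(n_cells),
                                 clearing_px),
    seed = seed)
  cells <- make_grid_cells(ls, cell_px)
  beta1_grid <- NULL
  if (!is.null(beta1_cells)) {
    if (length(beta1_cells) != nrow(cells))
      stop("beta1_cells must have one value per cell")
    beta1_grid <- matrix(NA_real_, shape[1], shape[2])
    for (i in seq_len(nrow(cells)))
      beta1_grid[cells$row_min[i]:cells$row_max[i],
                 cells$col_min[i]:cells$col_max[i]] <- beta1_cells[i]
  }
  ls <- generate_biomass(ls, truth, beta1_grid = beta1_grid)
  list(landscape = ls, cells = cells, truth = truth)
}

#' Simulate one cell's sampled points directly
#'
#' Point-level shortcut past the raster stage: draws point coordinates
#' uniformly in a square cell, distances-to-edge log-uniformly, and biomass
#' from the plateaued log-linear truth with optional iid and spatially
#' correlated noise (exponential covariance over point coordinates).
#' Useful for regression-property studies where the raster substrate is
#' irrelevant.
#'
#' @param n Number of points.
#' @param beta0,beta1,depth_star Truth parameters as in [landscape_truth()].
#' @param noise_sd iid noise sd (Mg ha^-1).
#' @param spatial_sd,spatial_range Optional Gaussian-process residual
#'   component: marginal sd (Mg ha^-1) and exponential-covariance range (m).
#' @param d_range Distance-to-edge range (m); sampled log-uniformly.
#' @param extent Cell side (m) for coordinates.
#' @param cell_id Cell identifier stamped on the points.
#' @param seed Integer seed.
#' @return A point data frame with columns `cell_id`, `x`, `y`,
#'   `distance_m`, `agb_mg_ha`, `cover_pct`.
#' @export
simulate_cell_points <- function(n = 500, beta0 = 50, beta1 = 50,
                                 depth_star = Inf, noise_sd = 15,
                                 spatial_sd = 0, spatial_range = 500,
                                 d_range = c(30, 1000), extent = 3000,
                                 cell_id = 1L, seed = 1L) {
  set.seed(seed)
  x <- stats::runif(n, 0, extent)
  y <- stats::runif(n, 0, extent)
  d <- 10^stats::runif(n, log10(d_range[1]), log10(d_range[2]))
  mu <- beta0 + beta1 * log10(pmin(d, depth_star))
  e <- stats::rnorm(n, sd = noise_sd)
  if (spatial_sd > 0) {
    dm <- as.matrix(stats::dist(cbind(x, y)))
    S <- spatial_sd^2 * exp(-dm / spatial_range)
    diag(S) <- diag(S) + 1e-8
    e <- e + drop(chol(S) %*% stats::rnorm(n))
  }
  data.frame(cell_id = cell_id, x = x, y = y, distance_m = d,
             agb_mg_ha = pmax(0, mu + e),
             cover_pct = stats::runif(n, 30, 100))
}

#' Simulate per-cell environmental covariates
#'
#' Draws one row per grid cell of the seven covariates used for driver
#' attribution, with independent uniform marginals over field-realistic
#' ranges, and places cells on a planar lattice (coordinates in cell-width
#' units) for spatially buffered cross-validation.
#'
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed.
#' @return Data frame with `cell_id`, `x`, `y` and covariates `mat` (deg C),
#'   `map` (mm/yr), `wind` (m/s), `soil_moisture` (volumetric fraction),
#'   `elevation` (m), `slope` (degrees), `agriculture` (percent).
#' @export
simulate_cell_covariates <- function(n_cells, seed = 1L) {
  set.seed(seed)
  w <- ceiling(sqrt(n_cells))
  i <- seq_len(n_cells) - 1L
  data.frame(
    cell_id = seq_len(n_cells),
    x = i %% w + stats::runif(n_cells, -0.25, 0.25),
    y = i %/% w + stats::runif(n_cells, -0.25, 0.25),
    mat = stats::runif(n_cells, -5, 28),
    map = stats::runif(n_cells, 200, 3500),
    wind = stats::runif(n_cells, 1, 8),
    soil_moisture = stats::runif(n_cells, 0.05, 0.45),
    elevation = stats::runif(n_cells, 0, 3000),
    slope = stats::runif(n_cells, 0, 30),
    agriculture = stats::runif(n_cells, 0, 100))
}

#' Generate covariates with planted effects on the edge-effect slope
#'
#' Produces the attribution test substrate: a covariate table plus a true
#' per-cell slope `beta1_true = sum_j f_j(covariate_j) + noise`, so the
#' driver-attribution stage has a known importance ordering to recover.
#'
#' @param n_cells Number of cells (>= 30).
#' @param effects Named list mapping covariate names (columns of the
#'   covariate table) to vectorised response functions.
#' @param noise_sd sd of iid noise added to the true slope.
#' @param seed Integer seed.
#' @param covariates Optional covariate table; defaults to
#'   [simulate_cell_covariates()].
#' @return List with `covariates` (data frame) and `beta1_true` (numeric).
#' @export
generate_attribution_truth <- function(n_cells = 200,
                                       effects = list(
                                         mat = function(v) 1.5 * v,
                                         agriculture = function(v) 0.25 * v,
                                         map = function(v) 0.005 * v),
                                       noise_sd = 5, seed = 1L,
                                       covariates = NULL) {
  if (n_cells < 30) stop("n_cells must be >= 30")
  if (is.null(covariates))
    covariates <- simulate_cell_covariates(n_cells, seed = seed)
  unknown <- setdiff(names(effects), names(covariates))
  if (length(unknown) > 0)
    stop("unknown covariate name(s) in effects: ",
         paste(unknown, collapse = ", "))
  set.seed(seed + 1L)
  signal <- rowSums(vapply(names(effects),
                           function(nm) effects[[nm]](covariates[[nm]]),
                           numeric(nrow(covariates))))
  list(covariates = covariates,
       beta1_true = signal + stats::rnorm(nrow(covariates), sd = noise_sd))
}
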