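#' Depth of edge influence for one cell
#'
#' The distance threshold separating edge from interior forest, estimated
#' as the mean distance-to-edge of the cell's highest-biomass points. Two
#' readings of "points with the 90th percentile of biomass" are supported:
#' `mode = "top"` (default) takes all points with biomass at or above the
#' 90th percentile (top decile); `mode = "band"` takes points whose biomass
#' falls between the `percentile - band` and `percentile + band` quantiles.
#' The mode used is recorded on the result.
#'
#' @param points Point data frame for one retained cell.
#' @param percentile Biomass percentile (default 0.9).
#' @param mode `"top"` or `"band"`.
#' @param band Percentile half-width for `mode = "band"` (default 0.05).
#' @param min_points Minimum qualifying points (default 5); fewer is an
#'   error.
#' @return Depth of edge influence in metres, with attributes `mode` and
#'   `n_qualifying`.
#' @export
depth_of_edge_influence <- function(points, percentile = 0.9,
                                    mode = c("top", "band"), band = 0.05,
                                    min_points = 5) {
  mode <- match.arg(mode)
  b <- points$agb_mg_ha
  if (mode == "top") {
    qual <- b >= stats::quantile(b, percentile)
  } else {
    lo <- stats::quantile(b, max(0, percentile - band))
    hi <- stats::quantile(b, min(1, percentile + band))
    qual <- b >= lo & b <= hi
  }
  if (sum(qual) < min_points)
    stop("only ", sum(qual), " qualifying points (minimum ", min_points,
         "); cell flagged")
  d_star <- mean(points$distance_m[qual])
  attr(d_star, "mode") <- mode
  attr(d_star, "n_qualifying") <- sum(qual)
  d_star
}

#' Counterfactual biomass account for one cell
#'
#' Converts per-pixel biomass density to stock (density times pixel area in
#' ha), then replaces the density of every edge pixel (distance strictly
#' below the depth of edge influence `d_star`) with the interior-equivalent
#' value `max(0, beta0 + beta1 * log10(d_star))`; interior pixels are
#' unchanged. Missing biomass is counterfactual minus actual stock. CI
#' bounds recompute the replacement with `beta1 +/- 1.96 * se_beta1`
#' (`beta0` held fixed). Replacement values clipped at zero are counted.
#'
#' @param biomass Numeric vector/matrix of the cell's biomass densities
#'   (Mg ha^-1; `NA` = non-forest).
#' @param distance Matching distances to edge (m).
#' @param estimate One-row data frame or list with `beta0`, `beta1`,
#'   `se_beta1`.
#' @param d_star Depth of edge influence (m); below the pixel resolution
#'   there are no edge pixels and missing biomass is 0, with a warning.
#' @param resolution Pixel side (m); pixel area is `resolution^2 / 1e4` ha.
#' @return One-row data frame: `d_star`, `actual_mg`, `counterfactual_mg`,
#'   `missing_mg`, `lower_mg`, `upper_mg`, `edge_pixels`, `forest_pixels`,
#'   `clipped_pixels`.
#' @export
counterfactual_cell <- function(biomass, distance, estimate, d_star,
                                resolution) {
  b <- as.numeric(biomass)
  d <- as.numeric(distance)
  ok <- !is.na(b) & !is.na(d)
  area_ha <- resolution^2 / 1e4
  actual <- sum(b[ok]) * area_ha
  edge <- ok & d < d_star
  if (d_star < resolution && sum(edge) == 0)
    warning("depth of edge influence below pixel resolution: no edge ",
            "pixels, missing biomass is 0")
  repl <- function(b1) {
    r <- estimate$beta0 + b1 * log10(d_star)
    c(density = max(0, r), clipped = as.integer(r < 0))
  }
  account <- function(b1) {
    r <- repl(b1)
    cf <- actual - sum(b[edge]) * area_ha +
      sum(edge) * r[["density"]] * area_ha
    c(counterfactual = cf, missing = cf - actual,
      clipped = r[["clipped"]] * sum(edge))
  }
  point <- account(estimate$beta1)
  lo <- account(estimate$beta1 - 1.96 * estimate$se_beta1)
  hi <- account(estimate$beta1 + 1.96 * estimate$se_beta1)
  data.frame(d_star = as.numeric(d_star),
             actual_mg = actual,
             counterfactual_mg = point[["counterfactual"]],
             missing_mg = point[["missing"]],
             lower_mg = min(lo[["missing"]], hi[["missing"]]),
             upper_mg = max(lo[["missing"]], hi[["missing"]]),
             edge_pixels = sum(edge), forest_pixels = sum(ok),
             clipped_pixels = point[["clipped"]])
}

#' Per-cell missing-biomass accounts over a landscape
#'
#' Runs [depth_of_edge_influence()] and [counterfactual_cell()] for every
#' cell with an estimate, reading pixel biomass and distances from the
#' landscape grids.
#'
#' @param landscape A `"forest_landscape"` with biomass and distance grids.
#' @param cells Cell table from [make_grid_cells()].
#' @param estimates Per-cell estimates from [fit_cells()].
#' @param points Point table (used for the depth of edge influence).
#' @param ... Passed to [depth_of_edge_influence()].
#' @return Data frame of per-cell accounts (`cell_id` + the columns of
#'   [counterfactual_cell()]); cells whose depth cannot be estimated are
#'   dropped with a warning.
#' @export
account_cells <- function(landscape, cells, estimates, points, ...) {
  mask <- classify_forest(landscape$cover, landscape$threshold)
  D <- landscape$distance
  if (is.null(D)) D <- distance_to_edge(mask, landscape$resolution)
  rows <- lapply(seq_len(nrow(estimates)), function(i) {
    id <- estimates$cell_id[i]
    cell <- cells[cells$cell_id == id, ]
    p <- points[points$cell_id == id, , drop = FALSE]
    ds <- tryCatch(depth_of_edge_influence(p, ...), error = function(e) {
      warning("cell ", id, ": ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(ds)) return(NULL)
    rr <- cell$row_min:cell$row_max
    cc <- cell$col_min:cell$col_max
    acc <- counterfactual_cell(landscape$biomass[rr, cc],
                               D[rr, cc], estimates[i, ], ds,
                               landscape$resolution)
    cbind(cell_id = id, acc)
  })
  do.call(rbind, rows)
}

#' Aggregate missing biomass to biome and global totals
#'
#' Sums per-cell accounts in petagrams (1 Pg = 1e9 Mg). Group CI bounds are
#' the sums of per-cell bounds (no covariance adjustment). The percent
#' difference is `missing / counterfactual * 100`.
#'
#' @param accounts Data frame from [account_cells()].
#' @param biome Optional biome label per account row; biome groups are
#'   reported in addition to the global total.
#' @return Data frame with `group`, `actual_pg`, `counterfactual_pg`,
#'   `missing_pg`, `lower_pg`, `upper_pg`, `percent`, `n_cells`.
#' @export
aggregate_missing <- function(accounts, biome = NULL) {
  stopifnot(nrow(accounts) >= 1)
  one <- function(rows, label) {
    a <- sum(rows$actual_mg) / 1e9
    cf <- sum(rows$counterfactual_mg) / 1e9
    data.frame(group = label, actual_pg = a, counterfactual_pg = cf,
               missing_pg = sum(rows$missing_mg) / 1e9,
               lower_pg = sum(rows$lower_mg) / 1e9,
               upper_pg = sum(rows$upper_mg) / 1e9,
               percent = 100 * sum(rows$missing_mg) / (cf * 1e9),
               n_cells = nrow(rows))
  }
  out <- one(accounts, "global")
  if (!is.null(biome))
    out <- rbind(out, do.call(rbind, lapply(unique(as.character(biome)),
      function(b) one(accounts[biome == b, , drop = FALSE], b))))
  out
}

#' Convert aboveground biomass to carbon
#'
#' Aboveground carbon is biomass times the wood carbon fraction (47.6%).
#' Including roots, total tree biomass is `agb / (1 - root_fraction)`
#' (roots assumed to be 22% of total tree biomass) before applying the
#' carbon fraction.
#'
#' @param agb Aboveground biomass (any mass unit; >= 0).
#' @param include_roots Add the belowground (root) share first?
#' @param carbon_fraction Wood carbon concentration, in (0, 1).
#' @param root_fraction Root share of total tree biomass, in (0, 1).
#' @return Carbon in the same unit as `agb`.
#' @export
biomass_to_carbon <- function(agb, include_roots = FALSE,
                              carbon_fraction = 0.476,
                              root_fraction = 0.22) {
  if (carbon_fraction <= 0 || carbon_fraction >= 1 ||
      root_fraction <= 0 || root_fraction >= 1)
    stop("fractions must lie in (0, 1)")
  if (any(agb < 0)) stop("agb must be >= 0")
  total <- if (include_roots) agb / (1 - root_fraction) else agb
  total * carbon_fraction
}
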