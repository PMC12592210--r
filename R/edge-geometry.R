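#' Classify forest pixels from percent tree cover
#'
#' A pixel is forest iff its cover is greater than or equal to the
#' threshold (inclusive boundary; the conventional definition is 30% cover
#' of trees taller than 5 m).
#'
#' @param cover Matrix of percent tree cover in `[0, 100]`.
#' @param threshold Percent threshold in `(0, 100]`.
#' @return Logical matrix; `TRUE` = forest. An all-`FALSE` mask is legal.
#' @export
classify_forest <- function(cover, threshold = 30) {
  stopifnot(is.matrix(cover), threshold > 0, threshold <= 100)
  if (min(cover) < 0 || max(cover) > 100)
    stop("cover values must lie in [0, 100]")
  cover >= threshold
}

#' Euclidean distance to the nearest forest edge
#'
#' For every forest pixel, the Euclidean distance in metres between its
#' centre and the centre of the nearest non-forest pixel (so the minimum
#' attainable distance is one resolution unit). Non-forest pixels carry
#' `NA`. Computed with the exact Euclidean distance transform of
#' \pkg{EBImage}.
#'
#' @param mask Logical matrix, `TRUE` = forest.
#' @param resolution Pixel side in metres.
#' @param border How pixels beyond the grid are treated: `"ignore"`
#'   (default; distances reference only observed non-forest pixels, and an
#'   all-forest mask yields `Inf` distances, flagged via the
#'   `"all_forest"` attribute) or `"nonforest"` (the grid border counts as
#'   edge).
#' @return Numeric matrix of distances (m), `NA` on non-forest.
#' @export
distance_to_edge <- function(mask, resolution,
                             border = c("ignore", "nonforest")) {
  border <- match.arg(border)
  stopifnot(is.matrix(mask), is.logical(mask), resolution > 0)
  all_forest <- all(mask)
  if (border == "nonforest") {
    padded <- matrix(FALSE, nrow(mask) + 2, ncol(mask) + 2)
    padded[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- mask
    d <- EBImage::distmap(padded * 1)[2:(nrow(mask) + 1),
                                      2:(ncol(mask) + 1)]
  } else if (all_forest) {
    d <- matrix(Inf, nrow(mask), ncol(mask))
  } else {
    d <- EBImage::distmap(mask * 1)
  }
  d <- matrix(as.numeric(d), nrow(mask), ncol(mask)) * resolution
  d[!mask] <- NA_real_
  attr(d, "all_forest") <- all_forest && border == "ignore"
  d
}

#' Tile a landscape into analysis grid cells
#'
#' Cells are non-overlapping `cell_px` x `cell_px` pixel blocks (row-major
#' order); blocks truncated at the landscape boundary are kept. In real-mode
#' analyses the cell extent is a parameter (the reference analysis used
#' 100 km x 100 km cells); in synthetic mode the default is a pixel block.
#'
#' @param landscape A `"forest_landscape"` (or any list with a `cover`
#'   matrix, `resolution` and `origin`).
#' @param cell_px Cell side in pixels.
#' @return Data frame with `cell_id`, pixel bounds (`row_min`, `row_max`,
#'   `col_min`, `col_max`) and planar bounds in metres (`xmin`, `xmax`,
#'   `ymin`, `ymax`).
#' @export
make_grid_cells <- function(landscape, cell_px = 96) {
  d <- dim(landscape$cover)
  res <- landscape$resolution
  org <- landscape$origin
  r0 <- seq(1, d[1], by = cell_px)
  c0 <- seq(1, d[2], by = cell_px)
  g <- expand.grid(row_min = r0, col_min = c0)
  g <- g[order(g$row_min, g$col_min), ]
  out <- data.frame(
    cell_id = seq_len(nrow(g)),
    row_min = g$row_min, row_max = pmin(g$row_min + cell_px - 1, d[1]),
    col_min = g$col_min, col_max = pmin(g$col_min + cell_px - 1, d[2]))
  # x follows columns, y follows rows (planar, origin at lower-left)
  out$xmin <- org[1] + (out$col_min - 1) * res
  out$xmax <- org[1] + out$col_max * res
  out$ymin <- org[2] + (out$row_min - 1) * res
  out$ymax <- org[2] + out$row_max * res
  out
}

#' Sample random points from forest pixels within each cell
#'
#' Draws up to `n_per_cell` forest pixels per cell uniformly without
#' replacement (capped at the available forest pixels; a cell with no
#' forest yields no points). Each point carries the pixel-centre
#' coordinates, distance to edge, biomass density and percent cover.
#'
#' @param landscape A `"forest_landscape"` with a biomass layer (see
#'   [generate_biomass()]); the distance grid is computed if absent.
#' @param cells Cell table from [make_grid_cells()].
#' @param n_per_cell Points per cell (default 500).
#' @param seed Integer seed; fixed seed reproduces the point set exactly.
#' @return Data frame of sample points: `cell_id`, `x`, `y` (m),
#'   `distance_m`, `agb_mg_ha`, `cover_pct`.
#' @export
sample_points <- function(landscape, cells, n_per_cell = 500, seed = 1L) {
  stopifnot(n_per_cell >= 1)
  mask <- classify_forest(landscape$cover, landscape$threshold)
  D <- landscape$distance
  if (is.null(D)) D <- distance_to_edge(mask, landscape$resolution)
  res <- landscape$resolution
  org <- landscape$origin
  set.seed(seed)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    rows <- cells$row_min[i]:cells$row_max[i]
    cols <- cells$col_min[i]:cells$col_max[i]
    sub <- mask[rows, cols, drop = FALSE]
    idx <- which(sub)
    if (length(idx) == 0) next
    take <- if (length(idx) > n_per_cell)
      sample(idx, n_per_cell) else idx
    r <- rows[(take - 1) %% length(rows) + 1]
    cl <- cols[(take - 1) %/% length(rows) + 1]
    gi <- cbind(r, cl)
    out[[i]] <- data.frame(
      cell_id = cells$cell_id[i],
      x = org[1] + (cl - 0.5) * res,
      y = org[2] + (r - 0.5) * res,
      distance_m = D[gi],
      agb_mg_ha = if (is.null(landscape$biomass)) NA_real_ else
        landscape$biomass[gi],
      cover_pct = landscape$cover[gi])
  }
  do.call(rbind, out)
}

#' Apply the cell-retention filters
#'
#' A cell is retained iff it contains strictly more than `min_points`
#' points and the fraction of its points within `near_dist` of an edge is
#' at least `near_frac` (a fraction of exactly `near_frac` is retained:
#' strict reading of "less than"). When `exclude_within > 0`, points with
#' distance `<= exclude_within` are removed first (mixed-pixel robustness
#' variant); filters are applied to the remaining points.
#'
#' @param points Point table from [sample_points()].
#' @param min_points Retain only cells with more than this many points
#'   (default 20).
#' @param near_frac Minimum fraction of points within `near_dist` of the
#'   edge (default 0.03).
#' @param near_dist Near-edge distance in metres (default 100).
#' @param exclude_within Drop points with distance <= this many metres
#'   before filtering (default 0 = keep all).
#' @return List with `points` (points of retained cells, after any
#'   `exclude_within` removal) and `cells`: an exclusion ledger with one
#'   row per cell (`cell_id`, `n_points`, `frac_near`, `retained`,
#'   `reason`), where `reason` is the first failing rule
#'   (`"too_few_points"`, then `"too_few_near_edge"`) or `""`.
#' @export
filter_cells <- function(points, min_points = 20, near_frac = 0.03,
                         near_dist = 100, exclude_within = 0) {
  if (exclude_within > 0)
    points <- points[points$distance_m > exclude_within, , drop = FALSE]
  ids <- sort(unique(points$cell_id))
  n <- vapply(ids, function(i) sum(points$cell_id == i), integer(1))
  frac <- vapply(ids, function(i) {
    d <- points$distance_m[points$cell_id == i]
    mean(d <= near_dist)
  }, numeric(1))
  enough <- n > min_points
  near <- frac >= near_frac
  ledger <- data.frame(
    cell_id = ids, n_points = n, frac_near = frac,
    retained = enough & near,
    reason = ifelse(!enough, "too_few_points",
                    ifelse(!near, "too_few_near_edge", "")))
  list(points = points[points$cell_id %in% ids[ledger$retained], ,
                       drop = FALSE],
       cells = ledger)
}
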