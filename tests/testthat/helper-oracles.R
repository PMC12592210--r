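# Exhaustive nearest-non-forest scan: the independent oracle for the
# Euclidean distance transform. O(N^2) on purpose.
brute_force_distance <- function(mask, resolution) {
  nf <- which(!mask, arr.ind = TRUE)
  d <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) {
        d[r, c] <- if (nrow(nf) == 0) Inf else
          sqrt(min((nf[, 1] - r)^2 + (nf[, 2] - c)^2)) * resolution
      }
    }
  }
  d
}

# Noiseless plateau points for depth-of-edge-influence checks.
plateau_points <- function(n = 400, beta0 = 50, beta1 = 50,
                           depth_star = 200, d_max = 360) {
  d <- seq(30, d_max, length.out = n)
  data.frame(cell_id = 1L, x = seq_len(n), y = rep(1, n), distance_m = d,
             agb_mg_ha = beta0 + beta1 * log10(pmin(d, depth_star)),
             cover_pct = 80)
}

# Minimal synthetic point table with a chosen near-edge count, for the
# retention-filter boundary cases.
toy_cell_points <- function(cell_id, n, n_near, near_dist = 100) {
  d <- c(rep(near_dist - 10, n_near), rep(near_dist + 400, n - n_near))
  data.frame(cell_id = cell_id, x = seq_len(n), y = rep(1, n),
             distance_m = d, agb_mg_ha = 100 + d / 10, cover_pct = 80)
}
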