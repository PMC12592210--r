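#' Trim extreme slope estimates
#'
#' Removes the `floor(tail_fraction * n)` smallest and largest `beta1`
#' values (per side). Ties are broken by row order, so the counts removed
#' are exact even with duplicated slopes.
#'
#' @param estimates Estimates data frame from [fit_cells()] (needs a
#'   `beta1` column).
#' @param tail_fraction Fraction trimmed from each tail (default 0.025).
#' @return The trimmed data frame, with attributes `n_removed_low` and
#'   `n_removed_high`.
#' @export
trim_outliers <- function(estimates, tail_fraction = 0.025) {
  stopifnot(tail_fraction >= 0, tail_fraction < 0.5)
  n <- nrow(estimates)
  k <- floor(tail_fraction * n)
  if (k == 0) {
    out <- estimates
  } else {
    ord <- order(estimates$beta1)
    drop <- c(ord[seq_len(k)], ord[seq.int(n - k + 1, n)])
    out <- estimates[-drop, , drop = FALSE]
  }
  attr(out, "n_removed_low") <- k
  attr(out, "n_removed_high") <- k
  out
}

#' Inverse-CV weighted summary of edge-effect slopes
#'
#' Weighted mean and weighted standard deviation of `beta1` per group, with
#' weights `1 / cv` (so better-determined slopes count more). Estimates
#' with undefined or non-positive CV are excluded and their count reported
#' in the `n_excluded` attribute.
#'
#' @param estimates Estimates data frame (columns `beta1`, `cv`).
#' @param group Optional grouping vector (e.g. biome labels) aligned with
#'   the rows; `NULL` summarises everything as `"global"`.
#' @return Data frame with `group`, `mean_beta1`, `sd_beta1`, `n_cells`.
#'   A single-estimate group returns its own `beta1` with sd 0. Empty
#'   groups (all CVs undefined) are absent from the output.
#' @export
weighted_summary <- function(estimates, group = NULL) {
  if (is.null(group)) group <- rep("global", nrow(estimates))
  ok <- is.finite(estimates$cv) & estimates$cv > 0
  n_excl <- sum(!ok)
  if (n_excl > 0)
    message(n_excl, " estimate(s) with undefined CV excluded from summary")
  est <- estimates[ok, , drop = FALSE]
  group <- group[ok]
  out <- do.call(rbind, lapply(unique(group), function(g) {
    b <- est$beta1[group == g]
    w <- 1 / est$cv[group == g]
    m <- sum(w * b) / sum(w)
    data.frame(group = g, mean_beta1 = m,
               sd_beta1 = sqrt(sum(w * (b - m)^2) / sum(w)),
               n_cells = length(b))
  }))
  if (is.null(out))
    out <- data.frame(group = character(0), mean_beta1 = numeric(0),
                      sd_beta1 = numeric(0), n_cells = integer(0))
  attr(out, "n_excluded") <- n_excl
  out
}

#' Classify the edge effect from the slope
#'
#' `beta1 > eps` is a negative edge effect (biomass lower near the edge),
#' `beta1 < -eps` a positive edge effect, and `|beta1| <= eps` negligible.
#' The three labels partition the real line.
#'
#' @param beta1 Numeric vector of slopes (finite).
#' @param eps Negligible-effect half-width (default 0.1).
#' @return Factor with levels `"negative"`, `"negligible"`, `"positive"`
#'   (edge-effect sense: `"negative"` means biomass loss near edges).
#' @export
classify_effect <- function(beta1, eps = 0.1) {
  stopifnot(all(is.finite(beta1)))
  factor(ifelse(beta1 > eps, "negative",
                ifelse(beta1 < -eps, "positive", "negligible")),
         levels = c("negative", "negligible", "positive"))
}
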