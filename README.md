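# forestedge

Quantifying forest edge effects on aboveground biomass (AGB), and what they
cost in carbon.

Forest fragmentation creates edges, and biomass density near an edge
usually differs from the forest interior — with consequences for carbon
stock accounting that are routinely ignored. `forestedge` implements a
raster-to-carbon analysis pipeline for this problem, aimed at landscape
ecologists and carbon-accounting researchers working with co-registered
forest-cover and biomass maps (or, by default, with synthetic fragmented
landscapes whose ground truth is known).

## The model

Within each spatial grid cell, sampled forest locations are fit with a
log-linear edge-effect regression

```
Y = β₀ + β₁ · log₁₀(D) + ε
```

where `Y` is AGB density (Mg ha⁻¹) and `D` the Euclidean distance (m) from
the point to the nearest non-forest pixel. The slope `β₁` — written
ΔAGB/ΔD — is the edge effect: `β₁ > 0` means biomass is lower near edges
(a negative edge effect in the ecological sense). Residual spatial
autocorrelation within a cell is absorbed by Moran eigenvector filtering:
eigenvectors of the doubly-centred k-nearest-neighbour connectivity matrix
are added greedily until residual Moran's I is no longer significant under
a permutation test.

Around that estimator the package provides:

- **Edge geometry** — forest classification at a cover threshold (default
  30%), an exact Euclidean distance-to-edge transform, gridded random point
  sampling, and the cell retention filters (more than 20 points; at least
  3% of points within 100 m of an edge).
- **Summaries** — 2.5%-per-tail trimming of slopes, inverse-CV weighted
  biome/global means, and effect classification (negligible when
  |β₁| ≤ 0.1).
- **Driver attribution** — Spearman/VIF collinearity screening, inverse-CV
  weighted XGBoost regression of β₁ on environmental covariates (MAT, MAP,
  wind, soil moisture, elevation, slope, agriculture), exact TreeSHAP
  values, and spatially buffered leave-one-out cross-validation.
- **Carbon accounting** — per-cell depth of edge influence `D*` (mean
  distance of the top-decile-biomass points), a counterfactual in which
  every pixel closer than `D*` carries the interior-equivalent density
  `β₀ + β₁·log₁₀(D*)`, missing biomass (counterfactual − actual) with
  1.96·SE slope-propagated confidence bounds, and biomass→carbon
  conversion (47.6% wood carbon; roots as 22% of total tree biomass).
- **Synthetic landscapes** — fragmented cover grids and plateaued
  log-linear biomass fields with known `β₀`, `β₁`, `D*` and noise, so every
  stage has a parameter-recovery test.

## Worked example

```r
library(forestedge)

syn <- synthetic_landscape(n_cells = c(2, 3),
                           truth = landscape_truth(seed = 20), seed = 10)
pts <- sample_points(syn$landscape, syn$cells, n_per_cell = 500, seed = 30)
flt <- filter_cells(pts)

fit <- edge_lm(flt$points[flt$points$cell_id == 1, ], seed = 40)
fit
#> Spatially filtered edge-effect regression (biomass)
#>   beta1 (dAGB/dD): 41.04  (se 2.34, cv 0.0569)
#>   beta0: 68.39   n = 500 points
#>   eigenvectors used: 8   residual Moran's I: 0.166 (p=0.005) -> 0.037 (p=0.050)

est <- fit_cells(flt$points, seed = 40)
weighted_summary(trim_outliers(est))
#>    group mean_beta1 sd_beta1 n_cells
#> 1 global   43.62034   4.2335       6

acc <- account_cells(syn$landscape, syn$cells, est, flt$points)
aggregate_missing(acc)[, c("group", "missing_pg", "percent")]
#>    group   missing_pg  percent
#> 1 global 4.621845e-05 6.427121
```

Reading the output: cell 1 loses about 41 Mg ha⁻¹ of biomass density per
decade of distance towards the edge (a strong negative edge effect; the
generating slope was 50 with a 300 m plateau, so some attenuation is
expected), the landscape-wide inverse-CV weighted mean is ≈ 44, and edge
effects have removed ≈ 6.4% of the biomass this landscape would carry if
edge pixels held interior density. `biomass_to_carbon()` converts such
totals to Pg C.

The whole chain — including the attribution stage — also runs as one call:

```r
run_pipeline(default_config(seed = 1, outdir = "run1"))
```

or from a shell via `inst/scripts/forestedge-pipeline.R`. Stage artifacts
(points, estimates, SHAP tables, accounts, totals, report plots) land in
the output directory as CSV/JSON/TIFF.

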