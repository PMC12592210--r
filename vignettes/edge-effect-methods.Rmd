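---
title: "Methods: estimating forest edge effects and missing biomass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating forest edge effects and missing biomass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
model, its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic-landscape generator does and does not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The edge-effect model

Forest fragmentation exposes formerly interior forest to edge conditions —
altered microclimate, wind, fire and human pressure — whose net outcome on
aboveground biomass (AGB) density we call the edge effect. Within one grid
cell, sampled forest locations are modelled as

$$Y = \beta_0 + \beta_1 \log_{10} D + \varepsilon,$$

with $Y$ the AGB density (Mg ha$^{-1}$) and $D$ the Euclidean distance (m)
to the nearest non-forest pixel. The log transform encodes the assumption
that edge influence is strongest in the first tens of metres and fades
with distance; $\beta_1$ (units Mg ha$^{-1}$ per log$_{10}$ m) is the edge
effect, positive when biomass is depressed near edges. The model is
deliberately covariate-free: within a cell the regression measures the
realised edge effect, and environmental drivers enter only downstream,
where they explain *between*-cell variation in $\beta_1$.

Assumptions worth stating:

- points within a cell share a single edge-effect slope;
- distances are planar (an equal-area projected grid in real mode);
- the minimum observable distance is one pixel (distances are measured
  centre-to-centre, so a forest pixel adjacent to a clearing is 30 m from
  it at 30 m resolution).

## Spatial filtering

Residuals of nearby points are correlated (stand history, soils,
topography), which biases ordinary-least-squares standard errors. The fit
therefore uses Moran eigenvector filtering:

1. A k-nearest-neighbour graph (default `k = 8`) on the point coordinates
   is row-standardised and symmetrised; the same weights serve Moran's I
   and the eigenvector construction.
2. If a one-sided permutation test (199 permutations, seeded; default
   `alpha = 0.05`) finds significant positive residual Moran's I in the
   OLS fit, eigenvectors of the doubly-centred connectivity matrix are
   considered as extra regressors. Candidates are vectors with Moran's I
   above 0.1; selection is greedy-forward, each step taking the candidate
   that most reduces the absolute residual Moran's I, and is
   improvement-gated, so filtering can never increase it. Selection stops
   when the permutation test is non-significant, no candidate improves, or
   a cap (default 50 vectors) is hit.
3. With zero selected vectors the fit *is* OLS, exactly — a property the
   test suite asserts on coefficients and standard errors.

The eigenvector machinery is built lazily: most cells with well-behaved
residuals never pay for the eigendecomposition. The slope's coefficient of
variation is defined as $\mathrm{se}(\beta_1)/|\beta_1|$ (the standard
definition; undefined at $\beta_1 = 0$, in which case the cell is excluded
from weighted summaries with a logged count). Biome and global means of
$\beta_1$ are weighted by $1/\mathrm{CV}$, the meta-analytic convention
that favours better-determined estimates; the weighted sd uses the same
weights. Before summarising, the extreme 2.5% of slopes per tail are
trimmed (`floor(0.025 n)` from each side, ties broken by row order so the
removed counts are exact). Slopes are classified negligible when
$|\beta_1| \le 0.1$.

## Sampling and retention rules

Up to 500 random forest pixels per cell are sampled uniformly without
replacement (capped at the available pixels — the replacement policy is a
package choice, as sampling-with-replacement would duplicate pixel values
without adding information). Cells are retained only if they hold strictly
more than 20 points and at least 3% of their points lie within 100 m of an
edge; a fraction of exactly 3% is retained (strict reading of "less
than"). A robustness variant first removes points within 30 m of an edge
(mixed pixels). The exclusion ledger records one reason per dropped cell —
the first failing rule — so the reasons partition the dropped set.

Two open readings are supported as configuration rather than resolved
silently: out-of-grid pixels may be treated as non-forest
(`distance_to_edge(border = "nonforest")`) or ignored (default, in which
case an all-forest mask yields infinite distances and a flag); and points
may be drawn from forest pixels only (default) or from all pixels and then
filtered, which is equivalent here because non-forest pixels carry no
biomass value.

## Driver attribution

Between-cell variation in $\beta_1$ is attributed to seven per-cell
covariates: mean annual temperature (°C), mean annual precipitation
(mm yr$^{-1}$), wind speed (m s$^{-1}$), soil moisture (volumetric
fraction), elevation (m), slope (degrees) and percent
cultivated/managed vegetation. Before fitting, covariates are screened:
all pairwise Spearman correlations and VIFs are reported; pairs with
$|\rho| \ge 0.7$ lose the member with the larger mean $|\rho|$ against the
rest, then covariates with VIF $\ge 3$ are dropped largest-first. Both
rules are deterministic, making the screen idempotent.

The model is an XGBoost regression, trained on a seeded 80/20 split with
each training point weighted by $1/\mathrm{CV}$ of its slope estimate.
Hyperparameters (tree depth 2–8, learning rate $10^{-2}$–$10^{-0.5}$, row
and column subsampling 0.5–1, minimum child weight 1–10, L2 penalty
$10^{-1}$–$10^{1}$) are tuned by seeded Latin-hypercube random search —
the package's tuner of choice for a deterministic, dependency-light
search — scoring each candidate on an inner 75/25 validation split with
early stopping, then refitting on the full training set. Hold-out RMSE,
$R^2 = 1 - \mathrm{SSE}/\mathrm{SST}$ and MAE are reported.

Because $\beta_1$ is spatially smooth, plain cross-validation can reward
spatial leakage rather than environmental signal. The package therefore
also evaluates models by spatially buffered leave-one-out CV: for each
held-out cell, training excludes everything within a buffer radius, and
predictions are pooled into one $R^2$. Default radii are 0, 1, 2 and 5
cell-widths in synthetic mode (real-mode radii in km are configuration);
buffer 0 reduces to plain leave-one-out by construction. Folds with no
training data are skipped and counted.

Interpretation uses exact TreeSHAP contributions: per cell and covariate,
the additive share of the predicted $\beta_1$. Mean $|\mathrm{SHAP}|$
ranks covariates globally; dependence tables pair covariate values with
their SHAP values plus an interaction colouring column. Biome-level models
repeat screen + fit + SHAP per biome, excluding cells that straddle more
than one biome and skipping biomes with fewer than 25 cells. The purpose
throughout is attribution, not prediction of unobserved cells.

## Missing biomass

The carbon question is counterfactual: how much AGB would the landscape
hold if edge areas carried interior-equivalent density? Edge is separated
from interior per cell by the depth of edge influence $D^*$, estimated as
the mean distance-to-edge of the points with top-decile biomass. The
phrase "points with the 90th percentile of biomass" admits two readings,
both implemented and recorded in outputs: all points at or above the 90th
percentile (default), or points within a percentile band around it
(`mode = "band"`). For each cell, pixels with $D < D^*$ (strictly — a
pixel exactly at $D^*$ is interior) have their density replaced by
$\max(0,\ \beta_0 + \beta_1\log_{10} D^*)$, clip events counted; stocks
are density × pixel area (resolution$^2$/10$^4$ ha). Missing biomass is
counterfactual minus actual stock; totals are reported in Pg (10$^9$ Mg)
and as a percentage of the counterfactual.

Uncertainty propagates the slope standard error only: bounds recompute
the replacement with $\beta_1 \pm 1.96\,\mathrm{se}$, holding $\beta_0$
fixed (the filtered-model intercept), and group bounds are sums of
per-cell bounds with no covariance adjustment — both choices are stated
in output metadata. Carbon conversion multiplies AGB by a 47.6% wood
carbon fraction; including roots, total tree biomass is AGB/(1 − 0.22)
first.

## The synthetic-landscape generator

Synthetic mode is a first-class module, not a fixture: it generates the
conditions under which every downstream stage is tested against known
truth. Its defaults are fixed study conditions:

- 30 m pixels, 96 × 96-pixel cells, 500 points per cell;
- noiseless biomass $\beta_0 + \beta_1\log_{10}(\min(D, D^*))$ with
  $\beta_0 = 50$ Mg ha$^{-1}$, $\beta_1 = 50$ Mg ha$^{-1}$ per
  log$_{10}$ m (a strong, tropical-scale edge effect) and a plateau at
  $D^* = 300$ m, near reported global mean depths of edge influence;
- noise = white (sd 15 Mg ha$^{-1}$) plus a spatially correlated
  component (sd 8 Mg ha$^{-1}$, 120 m range), implemented as
  Gaussian-kernel-smoothed white noise on a torus and rescaled — the
  kernel, not an explicit covariance family, defines the correlation
  structure; negative biomass is clipped at 0 and every clip counted;
- fragmentation via 12 random 12 × 12-pixel clearings per cell, set by
  perimeter arithmetic so that roughly 30% of forest pixels lie within
  100 m of an edge — the fragmentation level reported for global forests;
  thresholded correlated random fields and explicit rectangles are
  available alternatives;
- cover values are uniform in [threshold, 100] on forest and
  [0, threshold) elsewhere: only the mask matters downstream.

Identical seeds and parameters regenerate landscapes bit-identically.
Attribution truth is generated separately: per-cell covariates with
independent uniform marginals over field-realistic ranges, and a true
slope $\beta_{1}(\mathrm{cell}) = \sum_j f_j(\mathrm{covariate}_j) +
\mathrm{noise}$ for chosen response functions, so the planted importance
ordering is known. The pipeline couples the two by building the biomass
field with the per-cell planted slopes.

What the generator does **not** emulate: realistic biome geography,
cloud/terrain artefacts, biomass-map retrieval error structure (the noise
levels are free parameters, not calibrated to any product), temporal
change, or geodesy. Passing recovery tests therefore demonstrates that the
estimators recover the truth of *this* generating process at these noise
levels — not that a 30 m global product has those error properties.

## Numerical choices and degenerate inputs

- Distance transform: exact Euclidean distance via `EBImage::distmap()`,
  validated in-suite against an exhaustive $O(N^2)$ scan; all-forest masks
  yield `Inf` and a flag rather than an error.
- Eigenvectors: null-space vectors of the doubly-centred connectivity
  matrix are dropped (they carry no spatial signal), guaranteeing at most
  $n-1$ centred, mutually orthogonal vectors; orthogonality is asserted at
  $10^{-8}$.
- Moran's I of a zero-variance vector is defined as 0 (exact fits would
  otherwise produce 0/0).
- Perfect collinearity (constant distance), fewer than 10 points,
  non-positive distances, and duplicate-only coordinates are errors;
  constant biomass makes Spearman's $\rho$ undefined and is flagged.
- SHAP additivity is checked at $10^{-5}$ relative to prediction scale:
  xgboost sums leaf values in single precision, so this is its machine
  tolerance (double-precision exactness is not attainable), and the
  realised maximum is reported in every result object.
- Depth-of-edge-influence ties (e.g. a flat plateau or constant biomass)
  qualify every tied point, so a zero-slope cell returns the mean distance
  of all its points — distance-uninformative by construction.
- $D^*$ below the pixel resolution replaces nothing and warns; missing
  biomass is exactly 0.
- Trimming with $n < 1/\mathrm{fraction}$ removes nothing (floor counts).

## Problem sizes

The test suite and acceptance script run at sizes chosen as adequate for
their statistical purpose: 200 simulated cells × 500 points for slope bias
and CI coverage; 40 cells × 200 points with planted Gaussian-process
residuals (sd 15, range 800 m) for filtering efficacy; 10 seeds × 20-cell
landscapes (4 × 5 cells of 96² pixels) for end-to-end missing-biomass
recovery; 10 replicates × 120 cells for SHAP driver recovery; 30 random
40 × 40 masks for distance-transform equivalence. The full suite completes
in a few minutes on one CPU.

## Known limitations

- Real-mode rasters must share grid, resolution and an equal-area
  projection; the package does not reproject.
- Raster I/O uses plain TIFF with a JSON sidecar (scale factors,
  resolution, origin, truth); georeferencing beyond a planar origin is out
  of scope.
- The counterfactual propagates only slope uncertainty — biomass-map error
  and intercept uncertainty are not modelled.
- Group confidence bounds are sums of per-cell bounds, which ignores
  between-cell covariance and is therefore conservative in width relative
  to an independent-errors assumption.
- Attribution is interpretive: SHAP rankings describe the fitted model,
  not causal effects.
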