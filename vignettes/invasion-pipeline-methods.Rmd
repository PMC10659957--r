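---
title: "Methods: SDM ensembles, directional spread and diversity impact for an invading orb weaver"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SDM ensembles, directional spread and diversity impact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jorospread)
```

`jorospread` packages the three quantitative pillars of an early-invasion
assessment for the Jorō spider (*Trichonephila clavata*) in North America —
and, more generally, for any conspicuous invader tracked by community-science
occurrence data:

1. a **presence–background species distribution ensemble** trained on
   native-range occurrences and projected onto the introduced range;
2. **directional range-expansion estimation** from the invasion centroid, by
   leading-edge distances and kernel-density isopleth areas per compass
   quadrant;
3. a **diversity-impact analysis** of transect surveys, with AICc-ranked
   models of native orb-weaver richness and diversity against
   invasion-history covariates.

Every input can be generated synthetically with known ground truth, so the
whole pipeline is testable offline; this vignette records the models, the
parameters that matter, and the design decisions taken where the methodology
left choices open.

## Occurrence handling

Community-science records arrive as CSV exports with longitude, latitude and
an observation date. Cleaning drops unparseable or out-of-range rows (the
count is reported), deduplicates exact (lon, lat, date, species) repeats
across sources, and clips to a study extent. Extent membership is half-open,
`[min, max)` on both axes, so a point on a shared boundary belongs to exactly
one window.

Sampling effort in such data clusters around people, not spiders. The
standard correction, implemented in `thin_occurrences()`, keeps at most one
record per cell of the predictor grid (2.5 arc-min, roughly 4 km — so one
record per ~4 km² cell, letting thinning and value extraction share a single
grid). The within-cell choice is uniform-random, keyed on `(seed, cell id)`
rather than on a shared random stream: the choice made inside a cell does not
depend on which other cells are occupied, which makes thinning idempotent and
commutative with cell-aligned clipping — properties the test suite asserts.

Background points (default 50,000 per region, the conventional scale for
presence–background ensembles on continental extents) are drawn uniformly
over non-nodata cells; raster values are extracted by nearest (containing)
cell with no interpolation, the norm for bioclimate layers.

Because no raster I/O package is part of this package's dependency set,
gridded data travel in a lightweight in-memory container (`grid_layer`: a
matrix plus origin and square cell size, `NA` as nodata) with plain-text
Esri ASCII-grid read/write, a format GIS tools ingest directly.

## Climate comparison and predictor reduction

Native vs introduced climate is compared per predictor with Mann–Whitney
U tests and the rank-biserial correlation `r_rb = 1 − 2U/(n_x n_y)`
(midrank tie handling; two-sided normal-approximation p with tie-corrected
variance). Effects are called large when `|r_rb| > .5` and moderate above
`.3`.

Reduction of the 20 candidate predictors (19 bioclimate variables plus
maximum wind speed, the cell-wise maximum of the 12 monthly wind layers)
proceeds in two stages:

* **Ranking.** One bivariate logistic regression per predictor, on
  standardized values (standardizing first makes `|log OR|` comparable
  across predictors; ties break by column order). Complete separation yields
  an effectively infinite slope — flagged, ranked first; a fit that fails
  outright is flagged and ranked last.
* **Iterative removal.** While any surviving pair has `|Pearson r| > 0.7`,
  remove the single worst-ranked predictor involved in any such pair, then
  recompute. One removal per pass keeps the procedure faithful to
  "sequentially remove the lowest performing". The absolute correlation is
  used: a strong negative correlation is just as redundant as a positive
  one. The survivors provably contain no pair above the threshold.

## The four-model ensemble

All models receive centered-and-scaled predictors; the training means and
standard deviations are stored and re-applied when projecting onto a new
region (never re-estimated there).

* **GLM** — binomial regression with linear and quadratic terms per
  predictor. The quadratic term is the smallest structure that can express a
  climatic optimum; the exact term structure is this package's choice.
* **GAM** — `mgcv` binomial fit with one penalized thin-plate smooth per
  predictor (basis dimension `k = 5` by default).
* **maxent_like** — the penalized-logistic equivalent of a maximum-entropy
  model: linear, quadratic and hinge features (5 interior knots per
  predictor at training quantiles, forward and reverse), lasso penalty
  `λ = regmult · sqrt(log p / n_presence)` with hinge features penalized
  twice as hard. This is a universal-threshold-style default scaled by the
  presence count; a packaged Maxent's exact path is not re-specifiable
  bit-for-bit, so this model is validated by its properties (with linear
  features and `regmult = 0` it reproduces the linear GLM's suitability
  ranking). Background rows can be up-weighted via `background_weight`; the
  default is 1, since up-weighting shifts calibration (the intercept), not
  the ranking that every downstream use depends on.
* **downsampled_rf** — a 1000-tree classification random forest, `√p`
  candidate predictors per split, each tree's bootstrap drawing equal
  presence and background counts (the per-class size is the smaller class
  count). Down-sampling is what keeps the forest's votes from collapsing to
  the majority background class.

**Evaluation** is 10-fold spatial-block cross-validation: square blocks of
860 km tile the extent (degrees converted at the dataset mid-latitude),
blocks are shuffled and dealt round-robin to folds, and all points in a
block share a fold. Blocking prevents spatially autocorrelated test points
from leaking training information; on autocorrelated synthetic landscapes
block CV is measurably less optimistic than random-split CV, the designed
bias the method corrects (asserted as a tendency over 20 replicates in the
tests). Scores are AUC (Mann–Whitney rank form) and MAE against the 0/1
labels. Folds reduced to a single class are skipped and logged.

The final map is the equally weighted cell-wise mean of the four projected
suitability rasters; nodata in any input propagates.

## Directional range expansion

The invasion origin is the coordinate-wise mean of the earliest documented
introduction records (nine in the motivating study; they are a required
input, not package data). Observations are classified into NE/SE/NW/SW
half-plane quadrants with a north/east boundary convention (a point exactly
on the centroid is NE; the convention is logged, the choice is immaterial at
data scale).

* **Distance (leading edge).** Per year and quadrant, the mean great-circle
  distance (haversine, R = 6371.0088 km) of the up-to-three farthest
  records. An empty year-quadrant is missing, not zero; `n_used` reports how
  many records entered the mean. Least-squares slopes of distance on year
  give km/yr rates per direction.
* **Area (KDE isopleth).** Per year (per-calendar-year observation sets by
  default; a `cumulative` switch exists because either reading of "each
  year" is defensible), observations are thinned on the shared grid, then a
  bivariate Gaussian KDE with isotropic bandwidth
  `h = 0.5·(sd lon + sd lat)·n^(−1/6)` — the printed reference-bandwidth
  formula, which mixes degree-denominated standard deviations, so the KDE is
  computed in degree space — is evaluated on a 512×512 grid padded 4h beyond
  the data. The 0.99 isopleth is the grid-based highest-density region:
  cells sorted by density, cumulative mass cut at the level. Areas convert
  to km² per row of the grid with a cos-latitude factor (an equal-area
  correction applied after the degree-space KDE, trading geodesic purity for
  fidelity to the printed bandwidth formula), and are partitioned exactly by
  quadrant. Coincident points give `h = 0`, which is refused.

The KDE density agrees with `MASS::kde2d` (whose `h` argument is 4× the
kernel standard deviation) to numerical precision, and the 0.99-isopleth
area of a smoothed Gaussian cloud matches the closed form
`π·χ²₀.₉₉(2)·(σ² + h²)` within 10% at n = 10,000 — both asserted in tests.

## Diversity impact

Per transect: species richness, Shannon (natural log) and Simpson
(`1 − Σp²`) indices via `vegan`, all computed excluding the invader — its
locally enormous abundance would otherwise dominate the evenness terms.
(Richness excludes it too by default: the target quantity is *native*
diversity; a flag restores it.) Empty sites score zero on all three.

Invasion-history covariates: great-circle distance from the centroid
(reported in meters, matching the convention of the motivating analysis) and
`years_present` — a 10×10 km grid (built in a mid-latitude equal-distance
projection) records the first invader observation per cell; a survey point
inherits `as_of year − first year`, with a first observation in the as-of
year counting as 1 and an empty cell as 0 (integer-valued by this worked
rule; a fractional option is deliberately out of the default path).

Spatial autocorrelation of model residuals is tested with Moran's I under
two neighbor schemes: (A) k-nearest (k = 1), the minimal scheme guaranteeing
every location a neighbor, and (B) a 10 km radius with isolated locations
joined to their nearest neighbor. Weights are binary, row-standardized; the
p-value uses the kurtosis-adjusted randomization variance, two-sided.

The model suite crosses each response (richness: Poisson log-link;
Shannon/Simpson: Gaussian) with each historic predictor (distance, years)
and two structures (main effects; plus the `pop_density × predictor`
interaction with both main effects retained). The shared adjustment set —
temperature, windspeed, rain in the last 24 h, Julian day (1-based, from
January 1), human population density — encodes the causal analysis'
conclusion; the package deliberately contains no DAG machinery. Models are
ranked by `AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1)` within each response's suite
(the best model's ΔAICc is 0 by construction; `n ≤ k+1` is refused). Only
the interaction coefficient is surfaced by default — reporting every
adjustment coefficient invites the "table 2" misreading — with full tables
behind a flag. Scenario prediction pins named covariates, holds the rest at
sample means, and back-transforms Poisson responses with a delta-method
interval on the log scale.

## Synthetic data: what it emulates, and what it does not

The generators define the conditions all statistical claims are tested
under:

* `make_landscape()` — co-registered predictors as Gaussian random fields
  (white noise circularly convolved with a Gaussian kernel; length-scale in
  cells controls smoothness) and a true probability surface through a
  logistic link with known linear/quadratic coefficients.
* `sample_presences()` — cells drawn ∝ truth × an observer-bias surface
  (baseline plus Gaussian effort bumps), jittered within cells. Thinning a
  biased sample provably flattens the cluster share back to the
  occupied-cell share.
* `simulate_spread()` — per year and quadrant, points uniform over a disk
  sector whose radius grows linearly at that quadrant's rate (defaults NE
  40, NW 25, SE 10, SW 12 km/yr, 2000 points/yr over 2018–2022 — a
  north-faster-than-south pattern of the shape observed in the field). True
  edges ship as metadata; the leading-edge estimator recovers each rate
  within 15%.
* `simulate_surveys()` — 103 transects, 19-species pool (18 natives plus
  the invader), covariates in early-autumn ranges, `years_present` decaying
  with distance from the centroid, and native counts Poisson with log-mean
  following the suite equation on standardized covariates. The default true
  interaction (−0.20 standardized) was sized so the fitted interaction has
  median |z| ≈ 3 at n = 103 — clearly detectable, as the corresponding
  field analysis' interactions were at the same n — and frozen. The
  per-species mean (`exp(base_log_count) = 0.25`) gives realistic richness
  around 4 species per transect. `mode = "direct"` instead draws native
  richness itself from the Poisson model, making a Poisson regression on
  richness correctly specified; the estimator-unbiasedness test uses it.

What the generators do **not** emulate: the covariance structure of real
bioclimate layers (fields are independent), real observer behavior beyond
clustered effort, species' differential detectability, overdispersion in
counts, and temporal autocorrelation of surveys. Passing tests therefore
demonstrate correctness of the estimators under the stated generative
models, not field validity of any ecological conclusion.

## Problem sizes and numerical choices

The test suite and the acceptance script run on deliberately modest sizes —
landscapes of 10⁴–10⁵ cells, 2,000-point training tables, 10,000-point KDE
clouds, 100–500 replicate loops for statistical properties — chosen so the
full suite completes in well under a minute while leaving every assertion
statistically comfortable. Other fixed numerics: KDE evaluation grid 512
(256 in the yearly series helper), grid padding 4 bandwidths, glmnet lasso
path warm-started from 4λ, RF `ntree` 1000 by default (smaller in tests via
config), minimum 30 presences to fit an SDM, minimum 5 points per KDE year.

Reproducing a packaged Maxent or the original study's archived data snapshot
is out of scope offline; the four per-model CV statistics printed in the
motivating study are therefore benchmark context, not desk-scale assertions.
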