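# jorospread

Quantitative toolkit for assessing an early biological invasion from
community-science occurrence data, built around the Jorō spider
(*Trichonephila clavata*) invasion of the southeastern United States and
reusable for any conspicuous invader. Three analyses, one package:

1. **Species distribution ensemble.** Presence–background models trained on
   native-range occurrences — GLM (linear + quadratic), GAM (penalized
   smooths), a Maxent-equivalent penalized logistic model (linear, quadratic
   and hinge features, lasso penalty `λ = r·√(log p / n_presence)`), and a
   down-sampled 1000-tree random forest — evaluated by 10-fold
   spatial-block cross-validation (860 km blocks, AUC and MAE) and combined
   as an equally weighted average of projected suitability rasters.
2. **Directional range expansion.** From the invasion centroid (mean of the
   founding records), per year and compass quadrant: the leading edge as the
   mean haversine distance of the three farthest observations, and the
   occupied area as the 0.99 isopleth of a Gaussian KDE at the reference
   bandwidth `h = 0.5(sd lon + sd lat)·n^(−1/6)`, partitioned by quadrant
   in km².
3. **Diversity impact.** Native orb-weaver richness, Shannon and Simpson
   indices per transect (invader excluded); invasion-history covariates
   (distance from centroid, years present on a 10 km grid); Moran's I on
   residuals; and an AICc-ranked suite of Poisson/Gaussian models of the
   form `response ~ temp + windspeed + rain24h + julian_day +
   pop_density * predictor`, with scenario predictions.

A synthetic-data module (`make_landscape`, `sample_presences`,
`simulate_spread`, `simulate_surveys`) generates every input with known
ground truth, so the full pipeline runs and is tested entirely offline.

## Worked example

Simulate an invasion spreading at known direction-specific rates, then
recover those rates from the leading edge:

```r
library(jorospread)

sp   <- spread_spec()                     # NE 40, NW 25, SE 10, SW 12 km/yr
occs <- simulate_spread(sp, seed = 42)    # 2000 dated records per year, 2018-2022
series <- leading_edge_series(occs, sp$centroid)
expansion_rates(series)
#>    direction rate_km_per_yr n_years
#> NE        NE      39.795916       5
#> NW        NW      24.966942       5
#> SE        SE       9.984213       5
#> SW        SW      11.966389       5
```

The estimator recovers each generative rate within a fraction of a km/yr,
including the north-faster-than-south asymmetry. The same objects feed the
area method:

```r
yr2022 <- occs[format(occs$date, "%Y") == "2022", ]
kde <- kde_quadrant_areas(yr2022, sp$centroid, level = 0.99, grid_n = 256)
round(kde$quadrant_areas_km2)
#>     NE     SE     NW     SW
#>  36928   8509  18116   8283
```

— the 0.99-isopleth area in each quadrant (km²); the NE share is largest
because that direction expands fastest. Survey impact analysis, end to end:

```r
sv <- simulate_surveys(seed = 10)                 # 103 transects, known effects
suite <- fit_suite(sv, responses = "richness", predictors = "years_present")
suite[c("model", "aicc", "delta_aicc", "interaction_coef")]
#>                                model     aicc delta_aicc interaction_coef
#> 1        richness_years_present_main 421.3870    4.34879               NA
#> 2 richness_years_present_interaction 417.0382    0.00000     -0.002494923
```

AICc prefers the interaction model (ΔAICc 4.35 on the main-effects model),
and the fitted `pop_density × years` coefficient is negative: richness
declines where the invader has been longest, more steeply under high human
population density — exactly the structure the generator encodes.

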