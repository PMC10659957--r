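# Shared fixtures, built in code at test time.

# tiny raster with known values
toy_layer <- function(vals = matrix(1:12, 3, 4), xmin = 0, ymin = 0,
                      cs = 1, name = "toy") {
  grid_layer(vals, xmin, ymin, cs, name)
}

# labelled, standardized presence-background table from a strong
# one-predictor landscape; cached so several tests can share it
.sdm_cache <- new.env(parent = emptyenv())
strong_sdm_table <- function() {
  if (!is.null(.sdm_cache$tab)) return(.sdm_cache$tab)
  spec <- landscape_spec(
    predictors = list(temp_min = list(lengthscale = 15, variance = 1),
                      precip_season = list(lengthscale = 15, variance = 1)),
    beta = list(intercept = -12, linear = c(temp_min = 6, precip_season = 0),
                quadratic = c()))
  ls <- make_landscape(spec, seed = 11)
  occ <- sample_presences(ls$truth, 1000, seed = 12)
  bg <- sample_background(ls$layers[[1]], 1000, seed = 13)
  pres <- extract_values(cbind(occ[c("lon", "lat")], label = "presence"),
                         ls$layers)
  bgx <- extract_values(bg, ls$layers)
  cols <- c("lon", "lat", "label", "temp_min", "precip_season")
  std <- standardize_predictors(rbind(pres[cols], bgx[cols]))
  .sdm_cache$tab <- list(std = std, landscape = ls)
  .sdm_cache$tab
}

local_seed_test <- function(seed, expr) withr::with_seed(seed, expr)

# re-apply stored standardization parameters to raw extracted values
apply_std_test <- function(df, params) {
  for (i in seq_len(nrow(params))) {
    nm <- params$predictor[i]
    df[[nm]] <- (df[[nm]] - params$mean[i]) / params$sd[i]
  }
  df
}

# occurrences at exact great-circle distances due north of a centroid
occs_at_km <- function(centroid, dist_km, year = 2021L) {
  data.frame(
    record_id = sprintf("d%03d", seq_along(dist_km)),
    lon = centroid$lon,
    lat = centroid$lat + dist_km / (2 * pi * 6371.0088 / 360),
    date = as.Date(sprintf("%d-06-01", year)),
    species = "sp", source = "synthetic", stringsAsFactors = FALSE)
}
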