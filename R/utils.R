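# Shared internal helpers.

# Earth mean radius (km), IUGG value.
EARTH_RADIUS_KM <- 6371.0088

# km per degree of latitude (and of longitude at the equator).
KM_PER_DEG <- 2 * pi * EARTH_RADIUS_KM / 360

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so package functions never clobber user state.
local_seed <- function(seed, expr) {
  force(seed)   # before the snapshot: the caller may pass a random draw
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371.0088 km.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in decimal degrees (vectorized).
#' @return distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}
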