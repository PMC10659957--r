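#' Invasion centroid from founding records
#'
#' The origin for all directional spread measurements: the arithmetic mean
#' of the longitudes and latitudes of the earliest documented introduction
#' records (nine points in the motivating study).
#'
#' @param points data.frame with `lon`, `lat`.
#' @return list with `lon`, `lat`.
#' @export
compute_centroid <- function(points) {
  stopifnot(nrow(points) >= 1)
  list(lon = mean(points$lon), lat = mean(points$lat))
}

#' Compass quadrant of a point relative to the centroid
#'
#' North iff `lat >= centroid lat`, East iff `lon >= centroid lon` (points
#' exactly on a boundary, including the centroid itself, fall north/east by
#' convention).
#'
#' @param lon,lat point coordinates (vectorized).
#' @param centroid list with `lon`, `lat`.
#' @return character vector in `{"NE", "SE", "NW", "SW"}`.
#' @export
classify_quadrant <- function(lon, lat, centroid) {
  ns <- ifelse(lat >= centroid$lat, "N", "S")
  ew <- ifelse(lon >= centroid$lon, "E", "W")
  paste0(ns, ew)
}

#' Leading-edge distance for one year and direction
#'
#' The range edge is approximated by the mean great-circle distance from the
#' centroid of the (up to) three farthest observations in the given compass
#' quadrant during the given calendar year. With no qualifying observations
#' the distance is `NA` (missing, not zero).
#'
#' @param occs occurrence data.frame (`lon`, `lat`, `date`).
#' @param centroid list with `lon`, `lat`.
#' @param year calendar year.
#' @param direction one of `"NE"`, `"SE"`, `"NW"`, `"SW"`.
#' @param n_edge how many farthest observations to average (default 3).
#' @return data.frame `year`, `direction`, `distance_km`, `n_used`.
#' @export
leading_edge <- function(occs, centroid, year, direction, n_edge = 3L) {
  yr <- as.integer(format(occs$date, "%Y"))
  quad <- classify_quadrant(occs$lon, occs$lat, centroid)
  sel <- occs[yr == year & quad == direction, , drop = FALSE]
  if (!nrow(sel)) {
    return(data.frame(year = year, direction = direction,
                      distance_km = NA_real_, n_used = 0L))
  }
  d <- haversine_km(centroid$lon, centroid$lat, sel$lon, sel$lat)
  top <- utils::head(sort(d, decreasing = TRUE), n_edge)
  data.frame(year = year, direction = direction,
             distance_km = mean(top), n_used = length(top))
}

#' Leading-edge series over years and quadrants
#'
#' @param occs occurrence data.frame.
#' @param centroid list with `lon`, `lat`.
#' @param years integer vector of calendar years (default 2018:2022).
#' @param n_edge see [leading_edge()].
#' @return data.frame, one row per year x direction.
#' @export
leading_edge_series <- function(occs, centroid, years = 2018:2022,
                                n_edge = 3L) {
  grid <- expand.grid(year = years, direction = c("NE", "SE", "NW", "SW"),
                      stringsAsFactors = FALSE)
  do.call(rbind, Map(function(y, d) leading_edge(occs, centroid, y, d, n_edge),
                     grid$year, grid$direction))
}

#' Directional expansion rates from a leading-edge series
#'
#' Least-squares slope of distance on year, per direction (km/yr).
#'
#' @param series data.frame from [leading_edge_series()].
#' @return data.frame `direction`, `rate_km_per_yr`, `n_years`.
#' @export
expansion_rates <- function(series) {
  do.call(rbind, lapply(split(series, series$direction), function(s) {
    s <- s[!is.na(s$distance_km), , drop = FALSE]
    rate <- if (nrow(s) >= 2) {
      unname(stats::coef(stats::lm(distance_km ~ year, data = s))[2])
    } else {
      NA_real_
    }
    data.frame(direction = s$direction[1], rate_km_per_yr = rate,
               n_years = nrow(s), stringsAsFactors = FALSE)
  }))
}

#' Reference bandwidth for kernel density estimation
#'
#' `h = 0.5 * (sd(lon) + sd(lat)) * n^(-1/6)` in degrees, with the sample
#' (n-1) standard deviation — the classic reference (normal-scale) bandwidth
#' for a bivariate isotropic kernel.
#'
#' @param points data.frame with `lon`, `lat` (n >= 2).
#' @return bandwidth in degrees (0 if all points coincide; downstream KDE
#'   refuses h = 0).
#' @export
reference_bandwidth <- function(points) {
  stopifnot(nrow(points) >= 2)
  0.5 * (stats::sd(points$lon) + stats::sd(points$lat)) *
    nrow(points)^(-1 / 6)
}

#' Kernel density isopleth areas by quadrant
#'
#' Bivariate Gaussian KDE (isotropic kernel, sd = `h`, computed in degree
#' space) on a regular evaluation grid padded at least `4h` beyond the point
#' bounding box. The isopleth at `level` is the grid-based highest-density
#' region: cells are sorted by density and the smallest set containing
#' `level` of the integrated mass is kept. Its area, and the areas of its
#' intersections with the four half-plane quadrants at `centroid`, are
#' returned in km^2 using a per-row equal-area (cos-latitude) conversion.
#'
#' @param occs occurrence data.frame (`lon`, `lat`), already thinned.
#' @param centroid list with `lon`, `lat` splitting the plane into NE/SE/NW/SW.
#' @param level isopleth probability level in (0, 1), default 0.99.
#' @param h bandwidth in degrees; default [reference_bandwidth()].
#' @param grid_n evaluation grid cells per axis (default 512).
#' @param pad grid padding beyond the data bounding box, in bandwidths
#'   (default 4).
#' @return list: `lon`, `lat` (grid cell-center vectors), `density` (matrix,
#'   rows = lon, cols = lat), `h`, `level`, `threshold` (density cut),
#'   `total_area_km2`, `quadrant_areas_km2` (named NE/SE/NW/SW),
#'   `total_mass` (integrated density, ~1).
#' @export
kde_quadrant_areas <- function(occs, centroid, level = 0.99, h = NULL,
                               grid_n = 512L, pad = 4) {
  stopifnot(nrow(occs) >= 5)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  if (is.null(h)) h <- reference_bandwidth(occs)
  if (!is.finite(h) || h <= 0) {
    stop("bandwidth must be positive (coincident points give h = 0)",
         call. = FALSE)
  }
  x <- occs$lon; y <- occs$lat; n <- length(x)
  gx <- seq(min(x) - pad * h, max(x) + pad * h, length.out = grid_n)
  gy <- seq(min(y) - pad * h, max(y) + pad * h, length.out = grid_n)
  # product-kernel evaluation: (grid_n x n) %*% (n x grid_n) / n
  kx <- stats::dnorm(outer(gx, x, "-") / h) / h
  ky <- stats::dnorm(outer(gy, y, "-") / h) / h
  dens <- (kx %*% t(ky)) / n
  dx <- gx[2] - gx[1]; dy <- gy[2] - gy[1]
  mass <- dens * dx * dy
  total_mass <- sum(mass)
  ord <- order(dens, decreasing = TRUE)
  cum <- cumsum(mass[ord]) / total_mass
  cut_idx <- which(cum >= level)[1]
  threshold <- dens[ord[cut_idx]]
  inside <- dens >= threshold
  # equal-area conversion: cell area in km^2 shrinks with cos(latitude)
  cell_km2 <- matrix(rep(dx * dy * KM_PER_DEG^2 * cos(gy * pi / 180),
                         each = grid_n), nrow = grid_n)
  quad <- matrix(classify_quadrant(rep(gx, times = grid_n),
                                   rep(gy, each = grid_n), centroid),
                 nrow = grid_n)
  areas <- vapply(c("NE", "SE", "NW", "SW"), function(q) {
    sum(cell_km2[inside & quad == q])
  }, numeric(1))
  list(lon = gx, lat = gy, density = dens, h = h, level = level,
       threshold = threshold, total_area_km2 = sum(cell_km2[inside]),
       quadrant_areas_km2 = areas, total_mass = total_mass)
}

#' Yearly KDE quadrant areas
#'
#' Thins each year's observations on `grid` (same thinning as the occurrence
#' pipeline) and computes [kde_quadrant_areas()] per year. Years with fewer
#' than 5 thinned points are skipped with a message.
#'
#' @param occs occurrence data.frame with dates.
#' @param centroid list with `lon`, `lat`.
#' @param grid thinning [grid_layer()].
#' @param years calendar years (default 2018:2022).
#' @param level,h,grid_n passed to [kde_quadrant_areas()].
#' @param cumulative if `TRUE`, use all observations up to and including
#'   each year instead of that year only (default `FALSE`, per-year sets).
#' @param seed thinning seed.
#' @return data.frame `year`, `direction`, `area_km2`, `total_area_km2`.
#' @export
kde_area_series <- function(occs, centroid, grid, years = 2018:2022,
                            level = 0.99, h = NULL, grid_n = 256L,
                            cumulative = FALSE, seed = 1L) {
  yr <- as.integer(format(occs$date, "%Y"))
  rows <- list()
  for (y in years) {
    sel <- if (cumulative) occs[yr <= y, , drop = FALSE]
           else occs[yr == y, , drop = FALSE]
    sel <- thin_occurrences(sel, grid, seed = seed)
    if (nrow(sel) < 5) {
      message("year ", y, " skipped (<5 thinned points)")
      next
    }
    kde <- kde_quadrant_areas(sel, centroid, level = level, h = h,
                              grid_n = grid_n)
    rows[[length(rows) + 1L]] <- data.frame(
      year = y, direction = names(kde$quadrant_areas_km2),
      area_km2 = unname(kde$quadrant_areas_km2),
      total_area_km2 = kde$total_area_km2)
  }
  do.call(rbind, rows)
}
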