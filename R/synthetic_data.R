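# Synthetic inputs with known ground truth. These generators define the
# study conditions every pipeline stage is tested under: smooth multivariate
# suitability landscapes, spatially biased clustered occurrence sampling, a
# radially expanding invasion with direction-specific rates, and transect
# counts from a Poisson model with a density x predictor interaction.

# Smooth Gaussian random field on a grid: white noise convolved (circularly,
# via FFT) with a Gaussian kernel of the given length-scale in cells, then
# rescaled to mean 0, unit sd.
gaussian_field <- function(nr, nc, lengthscale) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (lengthscale <= 0) return(noise)
  di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
  dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
  kern <- exp(-outer(di^2, dj^2, "+") / (2 * lengthscale^2))
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern), inverse = TRUE)) /
    (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Specification for a synthetic predictor landscape
#'
#' @param ext an [extent()] (default a 10 x 8 degree window).
#' @param cellsize cell size in degrees (default 0.05).
#' @param predictors named list: per predictor a list with `lengthscale`
#'   (cells) and `variance`.
#' @param beta true suitability coefficients on the logit scale: `intercept`,
#'   named `linear` vector, named `quadratic` vector (missing names = 0).
#' @return a `landscape_spec` list.
#' @export
landscape_spec <- function(ext = extent(100, 30, 110, 38),
                           cellsize = 0.05,
                           predictors = list(
                             temp_min = list(lengthscale = 20, variance = 1),
                             precip_season = list(lengthscale = 15, variance = 1),
                             wind_max = list(lengthscale = 25, variance = 1)),
                           beta = list(intercept = -1,
                                       linear = c(temp_min = 2, precip_season = -1,
                                                  wind_max = 0),
                                       quadratic = c())) {
  structure(list(ext = ext, cellsize = cellsize, predictors = predictors,
                 beta = beta), class = "landscape_spec")
}

#' Generate a synthetic predictor landscape with known suitability
#'
#' Each predictor is a smooth Gaussian random field; the true occupancy
#' probability surface is `plogis(b0 + sum(b_i x_i) + sum(c_i x_i^2))`.
#' Reproducible under `seed`.
#'
#' @param spec a [landscape_spec()].
#' @param seed integer seed.
#' @return list: `layers` (named list of [grid_layer()]), `truth` (a
#'   `grid_layer` of probabilities in `[0, 1]`).
#' @export
make_landscape <- function(spec = landscape_spec(), seed = 1L) {
  ext <- spec$ext
  nc <- round((ext$max_lon - ext$min_lon) / spec$cellsize)
  nr <- round((ext$max_lat - ext$min_lat) / spec$cellsize)
  layers <- local_seed(seed, {
    lapply(spec$predictors, function(p) {
      gaussian_field(nr, nc, p$lengthscale) * sqrt(p$variance)
    })
  })
  layers <- Map(function(v, nm) {
    grid_layer(v, ext$min_lon, ext$min_lat, spec$cellsize, name = nm)
  }, layers, names(spec$predictors))
  eta <- matrix(spec$beta$intercept, nr, nc)
  for (nm in names(layers)) {
    b <- spec$beta$linear[nm]
    if (!is.na(b) && length(b)) eta <- eta + b * layers[[nm]]$values
    q <- spec$beta$quadratic[nm]
    if (!is.na(q) && length(q)) eta <- eta + q * layers[[nm]]$values^2
  }
  truth <- grid_layer(stats::plogis(eta), ext$min_lon, ext$min_lat,
                      spec$cellsize, name = "truth")
  list(layers = layers, truth = truth)
}

#' Sample presence records from a truth surface with observer bias
#'
#' Cells are drawn with probability proportional to
#' `truth x bias`, where the bias surface emulates clustered
#' community-science effort: a baseline plus Gaussian bumps around
#' "population centers". Points are jittered uniformly within their cell.
#'
#' @param truth a `grid_layer` of relative occupancy probability.
#' @param n number of presences.
#' @param bias `NULL` for uniform effort, or a list with `base` (scalar)
#'   and `centers` (data.frame `lon`, `lat`, `sd` (degrees), `weight`).
#' @param seed integer seed.
#' @param year calendar year stamped on the records (default 2021).
#' @param species species name.
#' @return occurrence data.frame (`record_id`, `lon`, `lat`, `date`,
#'   `species`, `source = "synthetic"`).
#' @export
sample_presences <- function(truth, n, bias = NULL, seed = 1L, year = 2021L,
                             species = "Trichonephila_clavata") {
  rows <- rep(seq_len(truth$nrow), each = truth$ncol)
  cols <- rep(seq_len(truth$ncol), times = truth$nrow)
  ctr <- cell_center(truth, rows, cols)
  w <- as.vector(t(truth$values))
  w[is.na(w)] <- 0
  if (!is.null(bias)) {
    b <- rep(bias$base, length(w))
    for (i in seq_len(nrow(bias$centers))) {
      cc <- bias$centers[i, ]
      d2 <- (ctr$lon - cc$lon)^2 + (ctr$lat - cc$lat)^2
      b <- b + cc$weight * exp(-d2 / (2 * cc$sd^2))
    }
    w <- w * b
  }
  local_seed(seed, {
    picks <- sample.int(length(w), n, replace = TRUE, prob = w)
    jx <- stats::runif(n, -0.5, 0.5) * truth$cellsize
    jy <- stats::runif(n, -0.5, 0.5) * truth$cellsize
    doy <- sample.int(365, n, replace = TRUE)
    data.frame(
      record_id = sprintf("synthetic-%06d", seq_len(n)),
      lon = ctr$lon[picks] + jx, lat = ctr$lat[picks] + jy,
      date = as.Date(sprintf("%d-01-01", year)) + doy - 1L,
      species = species, source = "synthetic", stringsAsFactors = FALSE)
  })
}

#' Specification for a simulated radial invasion
#'
#' @param centroid list `lon`, `lat` of the introduction point.
#' @param rates named vector of radial expansion rates km/yr for NE, SE,
#'   NW, SW.
#' @param years calendar years simulated.
#' @param n_per_year observations per year.
#' @param r0 initial envelope radius (km) in the year before `years[1]`.
#' @return a `spread_spec` list.
#' @export
spread_spec <- function(centroid = list(lon = -83.8, lat = 34.1),
                        rates = c(NE = 40, SE = 10, NW = 25, SW = 12),
                        years = 2018:2022, n_per_year = 2000L, r0 = 0) {
  stopifnot(all(rates >= 0), !is.unsorted(years))
  structure(list(centroid = centroid, rates = rates, years = years,
                 n_per_year = n_per_year, r0 = r0), class = "spread_spec")
}

#' Simulate a directionally expanding invasion
#'
#' Per year `y` and quadrant `q`, observations are placed uniformly over the
#' disk sector of radius `R_qy = r0 + rate_q * (y - min(years) + 1)` around
#' the centroid (radius `R * sqrt(U)`, angle uniform within the quadrant),
#' so the occupied envelope grows linearly at the quadrant's rate. The true
#' per-year, per-direction edge radii are attached as
#' `attr(, "true_edges")`.
#'
#' @param spec a [spread_spec()].
#' @param seed integer seed.
#' @return occurrence data.frame with dates spread through each year.
#' @export
simulate_spread <- function(spec = spread_spec(), seed = 1L) {
  quads <- c("NE", "NW", "SW", "SE")
  ang0 <- c(NE = 0, NW = pi / 2, SW = pi, SE = 3 * pi / 2)
  cen <- spec$centroid
  rows <- list(); edges <- list()
  local_seed(seed, {
    for (y in spec$years) {
      age <- y - min(spec$years) + 1
      nq <- table(sample(quads, spec$n_per_year, replace = TRUE))
      for (q in quads) {
        R <- spec$r0 + spec$rates[[q]] * age
        edges[[paste(y, q)]] <- data.frame(year = y, direction = q,
                                           true_edge_km = R)
        m <- if (q %in% names(nq)) nq[[q]] else 0L
        if (m == 0L) next
        r <- R * sqrt(stats::runif(m))
        a <- ang0[[q]] + stats::runif(m) * pi / 2
        dx <- r * cos(a); dy <- r * sin(a)
        rows[[paste(y, q)]] <- data.frame(
          lon = cen$lon + dx / (KM_PER_DEG * cos(cen$lat * pi / 180)),
          lat = cen$lat + dy / KM_PER_DEG,
          date = as.Date(sprintf("%d-01-01", y)) +
            sample.int(365, m, replace = TRUE) - 1L,
          stringsAsFactors = FALSE)
      }
    }
  })
  occs <- do.call(rbind, rows)
  occs <- data.frame(record_id = sprintf("spread-%06d", seq_len(nrow(occs))),
                     occs, species = "Trichonephila_clavata",
                     source = "synthetic", row.names = NULL,
                     stringsAsFactors = FALSE)
  attr(occs, "true_edges") <- do.call(rbind, c(edges, make.row.names = FALSE))
  occs
}

#' Specification for synthetic transect surveys
#'
#' True coefficients act on within-sample standardized covariates; the
#' response model is the diversity-suite equation (temperature, windspeed,
#' rain, Julian day, population density, historic predictor, and a
#' `pop_density x predictor` interaction) on the log of expected counts.
#' Defaults give a clearly detectable interaction at n = 103 (|z| ~ 3),
#' mirroring the scale of study in which such interactions were detectable.
#'
#' @param n_locations number of transects (default 103).
#' @param n_species species pool including the invader (default 19).
#' @param beta named list of true standardized-scale coefficients:
#'   `temp`, `wind`, `rain`, `jday`, `pop`, `pred`, `interaction`, plus
#'   `base_log_count` (per-species log expected count at covariate means).
#' @param centroid invasion centroid for distance/years covariates.
#' @param max_dist_km transect scatter radius around the centroid.
#' @return a `survey_spec` list.
#' @export
survey_spec <- function(n_locations = 103L, n_species = 19L,
                        beta = list(temp = 0.05, wind = -0.05, rain = -0.05,
                                    jday = 0.05, pop = -0.10, pred = -0.10,
                                    interaction = -0.20,
                                    base_log_count = log(0.25)),
                        centroid = list(lon = -83.8, lat = 34.1),
                        max_dist_km = 150) {
  structure(list(n_locations = n_locations, n_species = n_species,
                 beta = beta, centroid = centroid, max_dist_km = max_dist_km),
            class = "survey_spec")
}

#' Simulate transect surveys with known effects
#'
#' Locations are scattered around the invasion centroid; survey covariates
#' are drawn from ranges typical of early-autumn spider transects; the
#' `years_present` covariate decays with distance from the centroid (closer
#' sites were invaded earlier). Native species counts are Poisson with
#' log-mean following the suite equation with the spec's true coefficients
#' (`mode = "species"`: per-species counts; `mode = "direct"`: native
#' richness itself is the Poisson draw, so a Poisson regression on richness
#' is correctly specified for estimator-calibration checks). The invader's
#' count decays with distance and is generated separately.
#'
#' @param spec a [survey_spec()].
#' @param seed integer seed.
#' @param mode `"species"` or `"direct"` (see above).
#' @param predictor which historic covariate the true effect acts through:
#'   `"years_present"` (default) or `"distance_m"`.
#' @return data.frame with location, covariates, per-species counts
#'   (`count_*` columns), responses `richness`, `shannon`, `simpson`
#'   (invader excluded), and `attr(, "truth")` holding the spec.
#' @export
simulate_surveys <- function(spec = survey_spec(), seed = 1L,
                             mode = c("species", "direct"),
                             predictor = "years_present") {
  mode <- match.arg(mode)
  n <- spec$n_locations
  b <- spec$beta
  local_seed(seed, {
    ang <- stats::runif(n, 0, 2 * pi)
    dist_km <- spec$max_dist_km * sqrt(stats::runif(n))
    lon <- spec$centroid$lon + dist_km * cos(ang) /
      (KM_PER_DEG * cos(spec$centroid$lat * pi / 180))
    lat <- spec$centroid$lat + dist_km * sin(ang) / KM_PER_DEG
    temp_C <- stats::rnorm(n, 24, 4)
    windspeed_kph <- abs(stats::rnorm(n, 6, 4))
    rain24h_cm <- stats::rbinom(n, 1, 0.3) * stats::rexp(n, 1)
    date <- as.Date("2022-08-29") + sample.int(72, n, replace = TRUE) - 1L
    pop_density <- stats::rlnorm(n, meanlog = 4, sdlog = 0.7)
    years <- pmax(0, pmin(5, round(5 - dist_km / 30 + stats::rnorm(n, 0, 0.5))))
    covars <- data.frame(
      location_id = sprintf("site-%03d", seq_len(n)), lon = lon, lat = lat,
      date = date, temp_C = temp_C, windspeed_kph = windspeed_kph,
      rain24h_cm = rain24h_cm, julian_day = julian_day(date),
      pop_density = pop_density,
      distance_m = haversine_km(spec$centroid$lon, spec$centroid$lat,
                                lon, lat) * 1000,
      years_present = years, stringsAsFactors = FALSE)
    std <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
    pred_s <- std(covars[[predictor]])
    pop_s <- std(pop_density)
    eta <- b$temp * std(temp_C) + b$wind * std(windspeed_kph) +
      b$rain * std(rain24h_cm) + b$jday * std(covars$julian_day) +
      b$pop * pop_s + b$pred * pred_s + b$interaction * pop_s * pred_s
    n_native <- spec$n_species - 1L
    native_names <- sprintf("native_%02d", seq_len(n_native))
    counts <- matrix(0L, n, n_native, dimnames = list(NULL, native_names))
    if (mode == "species") {
      for (s in seq_len(n_native)) {
        counts[, s] <- stats::rpois(n, exp(b$base_log_count + eta))
      }
    } else {
      rich <- stats::rpois(n, pmin(exp(log(n_native * exp(b$base_log_count)) + eta),
                                   n_native))
      rich <- pmin(rich, n_native)
      for (i in seq_len(n)) {
        if (rich[i] > 0) {
          sp <- sample.int(n_native, rich[i])
          counts[i, sp] <- 1L + stats::rpois(rich[i], 1)
        }
      }
    }
    invader <- stats::rpois(n, 8 * exp(-dist_km / 40))
    all_counts <- cbind(counts, Trichonephila_clavata = invader)
    div <- diversity_metrics(all_counts)
    if (mode == "direct") div$richness <- apply(counts, 1, function(r) sum(r > 0))
    out <- cbind(covars, as.data.frame(all_counts), div)
    attr(out, "truth") <- list(spec = spec, predictor = predictor,
                               eta = eta)
    out
  })
}
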