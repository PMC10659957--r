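#' Diversity indices for one transect's counts
#'
#' Shannon (`H = -sum p_i log p_i`, natural log) and Simpson
#' (`D = 1 - sum p_i^2`) via [vegan::diversity()], plus species richness.
#' All-zero or empty counts give 0 for every index. The invading species is
#' excluded upstream (see [diversity_metrics()]).
#'
#' @param counts named non-negative integer vector (species -> count).
#' @return `shannon_index` / `simpson_index`: numeric.
#' @export
shannon_index <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  unname(vegan::diversity(counts, index = "shannon"))
}

#' @rdname shannon_index
#' @export
simpson_index <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  unname(vegan::diversity(counts, index = "simpson"))
}

#' Per-site diversity metrics, excluding the invader
#'
#' Richness, Shannon and Simpson per site. By default the invading species
#' is excluded from all three (its locally huge abundance would otherwise
#' drive the evenness terms and mask changes among natives).
#'
#' @param counts matrix or data.frame, sites x species.
#' @param invader column name of the invading species (dropped unless
#'   `exclude_invader = FALSE`).
#' @param exclude_invader default `TRUE`.
#' @return data.frame `richness`, `shannon`, `simpson`, one row per site.
#' @export
diversity_metrics <- function(counts, invader = "Trichonephila_clavata",
                              exclude_invader = TRUE) {
  m <- as.matrix(counts)
  if (exclude_invader && invader %in% colnames(m)) {
    m <- m[, colnames(m) != invader, drop = FALSE]
  }
  data.frame(
    richness = apply(m, 1, function(r) sum(r > 0)),
    shannon = apply(m, 1, shannon_index),
    simpson = apply(m, 1, simpson_index)
  )
}

#' Descriptive survey summary
#'
#' Per-species occupancy and abundance across all surveyed sites: number of
#' sites present, occupancy percentage, total individuals, and mean
#' individuals per surveyed site (total / number of sites).
#'
#' @param counts matrix or data.frame, sites x species.
#' @return data.frame `species`, `n_sites_present`, `occupancy_pct`,
#'   `total_count`, `mean_per_site`, sorted by decreasing occupancy.
#' @export
summarize_surveys <- function(counts) {
  m <- as.matrix(counts)
  n_sites <- nrow(m)
  out <- data.frame(
    species = colnames(m),
    n_sites_present = colSums(m > 0),
    occupancy_pct = 100 * colSums(m > 0) / n_sites,
    total_count = colSums(m),
    mean_per_site = colSums(m) / n_sites,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$occupancy_pct, out$species), ]
}

#' Years the invader has been present at a location
#'
#' Overlays a square grid (default 10 km edge, built in a mid-latitude
#' equal-distance projection of the survey extent) on the invader's
#' occurrence records, takes the first observation date in the cell
#' containing each survey point, and counts whole calendar years to `as_of`.
#' A first observation in the `as_of` calendar year counts as 1 (the animal
#' was present that season); a cell with no record gives 0.
#'
#' @param invader_occs occurrence data.frame (`lon`, `lat`, `date`).
#' @param points data.frame of survey locations (`lon`, `lat`).
#' @param as_of reference date (default `"2022-11-01"`).
#' @param grid_km grid edge length in km (default 10).
#' @return integer vector of years, one per survey point.
#' @export
years_present <- function(invader_occs, points, as_of = as.Date("2022-11-01"),
                          grid_km = 10) {
  as_of <- as.Date(as_of)
  all_lon <- c(invader_occs$lon, points$lon)
  all_lat <- c(invader_occs$lat, points$lat)
  mid_lat <- mean(range(all_lat))
  key <- function(lon, lat) {
    x <- lon * KM_PER_DEG * cos(mid_lat * pi / 180)
    y <- lat * KM_PER_DEG
    paste(floor((x - min(all_lon * KM_PER_DEG * cos(mid_lat * pi / 180))) / grid_km),
          floor((y - min(all_lat * KM_PER_DEG)) / grid_km))
  }
  occ_cell <- key(invader_occs$lon, invader_occs$lat)
  first_year <- vapply(split(invader_occs$date, occ_cell), function(d) {
    as.integer(format(min(d), "%Y"))
  }, integer(1))
  pt_cell <- key(points$lon, points$lat)
  as_of_year <- as.integer(format(as_of, "%Y"))
  vapply(pt_cell, function(cell) {
    if (!cell %in% names(first_year)) return(0L)
    max(1L, as_of_year - first_year[[cell]])
  }, integer(1), USE.NAMES = FALSE)
}

#' Julian day of year
#' @param date a `Date` vector.
#' @return integer day of year (Jan 1 = 1).
#' @export
julian_day <- function(date) {
  as.POSIXlt(as.Date(date))$yday + 1L
}

#' Neighbor weight matrices for Moran's I
#'
#' Scheme A (`knn`): each location is linked to its `k` nearest neighbors
#' (default 1), the minimal scheme ensuring every location has at least one
#' neighbor; links are symmetrized. Scheme B (`radius`): all locations
#' within `radius_km` are neighbors; an isolated location is joined to its
#' nearest neighbor with a message. Weights are binary then row-standardized.
#'
#' @param coords data.frame with `lon`, `lat`.
#' @param scheme `"knn"` or `"radius"`.
#' @param k neighbors for `knn` (default 1).
#' @param radius_km radius for `radius` (default 10).
#' @return row-standardized weight matrix.
#' @export
neighbor_weights <- function(coords, scheme = c("knn", "radius"), k = 1L,
                             radius_km = 10) {
  scheme <- match.arg(scheme)
  n <- nrow(coords)
  stopifnot(n >= 3)
  d <- outer(seq_len(n), seq_len(n), function(i, j) {
    haversine_km(coords$lon[i], coords$lat[i], coords$lon[j], coords$lat[j])
  })
  diag(d) <- Inf
  w <- matrix(0, n, n)
  if (scheme == "knn") {
    for (i in seq_len(n)) w[i, order(d[i, ])[seq_len(k)]] <- 1
    w <- pmax(w, t(w))                       # symmetrize: union of links
  } else {
    w[d <= radius_km] <- 1
    isolated <- which(rowSums(w) == 0)
    if (length(isolated)) {
      message(length(isolated), " isolated location(s) joined to nearest neighbor")
      for (i in isolated) {
        j <- which.min(d[i, ])
        w[i, j] <- 1; w[j, i] <- 1
      }
    }
  }
  w / rowSums(w)
}

#' Moran's I with randomization inference
#'
#' `I = (n / S0) * (sum_ij w_ij z_i z_j / sum_i z_i^2)` with centered
#' values `z`. Two-sided p-value from the normal approximation under the
#' randomization (permutation) null, using the standard
#' kurtosis-adjusted variance.
#'
#' @param values numeric vector (e.g. model residuals) at the locations.
#' @param weights weight matrix from [neighbor_weights()].
#' @return list `I`, `expected`, `sd`, `p_value`.
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  stopifnot(n >= 3, nrow(weights) == n, ncol(weights) == n)
  z <- values - mean(values)
  m2 <- sum(z^2)
  if (m2 == 0) stop("values have zero variance", call. = FALSE)
  s0 <- sum(weights)
  I <- (n / s0) * sum(weights * outer(z, z)) / m2
  e <- -1 / (n - 1)
  s1 <- 0.5 * sum((weights + t(weights))^2)
  s2 <- sum((rowSums(weights) + colSums(weights))^2)
  b2 <- n * sum(z^4) / m2^2
  v <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
          b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - e^2
  sd_I <- sqrt(v)
  p <- 2 * stats::pnorm(-abs((I - e) / sd_I))
  list(I = I, expected = e, sd = sd_I, p_value = p)
}

#' Small-sample corrected AIC
#'
#' `AICc = -2 logLik + 2k + 2k(k+1)/(n-k-1)`; requires `n > k + 1`.
#'
#' @param loglik log-likelihood.
#' @param k number of estimated parameters (including any scale parameter).
#' @param n sample size.
#' @return numeric.
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

suite_formula <- function(response, predictor, interaction) {
  base <- "temp_C + windspeed_kph + rain24h_cm + julian_day"
  tail <- if (interaction) {
    sprintf("pop_density * %s", predictor)
  } else {
    sprintf("pop_density + %s", predictor)
  }
  stats::as.formula(paste(response, "~", base, "+", tail))
}

#' Fit and AICc-rank the diversity model suite
#'
#' For each response (`richness` by Poisson log-link regression; `shannon`
#' and `simpson` by Gaussian linear model) and each historic-presence
#' predictor (`distance_m`, `years_present`), fits a main-effects model and
#' a model adding the `pop_density x predictor` interaction (both main
#' effects included). The shared adjustment set is temperature, windspeed,
#' rain in the last 24 h, Julian day and human population density. AICc and
#' within-response delta-AICc rank the suite.
#'
#' Only the interaction coefficient is surfaced by default (reporting every
#' adjustment coefficient invites the "table 2" misreading); set
#' `full_coefficients = TRUE` to attach complete summaries.
#'
#' @param data data.frame with columns `richness`, `shannon`, `simpson`,
#'   `temp_C`, `windspeed_kph`, `rain24h_cm`, `julian_day`, `pop_density`,
#'   `distance_m`, `years_present`.
#' @param responses subset of responses to fit (default all three).
#' @param predictors subset of `c("distance_m", "years_present")`.
#' @param full_coefficients attach full coefficient tables (default FALSE).
#' @return data.frame, one row per fitted model: `response`, `predictor`,
#'   `interaction`, `family`, `k`, `n`, `loglik`, `aicc`, `delta_aicc`,
#'   `interaction_coef`, `interaction_se`, `interaction_p`. The fitted model
#'   objects are in `attr(, "models")` (named list).
#' @export
fit_suite <- function(data,
                      responses = c("richness", "shannon", "simpson"),
                      predictors = c("distance_m", "years_present"),
                      full_coefficients = FALSE) {
  rows <- list(); models <- list()
  for (resp in responses) {
    family <- if (resp == "richness") "poisson" else "gaussian"
    for (pred in predictors) {
      for (inter in c(FALSE, TRUE)) {
        f <- suite_formula(resp, pred, inter)
        fit <- if (family == "poisson") {
          stats::glm(f, family = stats::poisson(), data = data)
        } else {
          stats::lm(f, data = data)
        }
        ll <- stats::logLik(fit)
        k <- attr(ll, "df")
        n <- nrow(data)
        term <- paste0("pop_density:", pred)
        sm <- summary(fit)$coefficients
        has <- inter && term %in% rownames(sm)
        id <- sprintf("%s_%s_%s", resp, pred,
                      if (inter) "interaction" else "main")
        models[[id]] <- fit
        rows[[id]] <- data.frame(
          model = id, response = resp, predictor = pred,
          interaction = inter, family = family, k = k, n = n,
          loglik = as.numeric(ll), aicc = aicc(as.numeric(ll), k, n),
          interaction_coef = if (has) sm[term, 1] else NA_real_,
          interaction_se = if (has) sm[term, 2] else NA_real_,
          interaction_p = if (has) sm[term, 4] else NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out$delta_aicc <- stats::ave(out$aicc, out$response,
                               FUN = function(a) a - min(a))
  rownames(out) <- NULL
  if (full_coefficients) {
    attr(out, "coefficients") <- lapply(models, function(m) summary(m)$coefficients)
  }
  attr(out, "models") <- models
  out
}

#' Predict a scenario from a fitted suite model
#'
#' Evaluates the model at the supplied covariate settings, holding every
#' unspecified covariate at its sample mean. Poisson responses are
#' back-transformed with a delta-method (log-scale normal) 95% interval.
#'
#' @param fit a model object from [fit_suite()]'s `attr(, "models")`.
#' @param scenario named list of covariate values to pin.
#' @param data the data the model was fitted on (for sample means).
#' @param level interval coverage (default 0.95).
#' @return data.frame `fit`, `lwr`, `upr` on the response scale.
#' @export
predict_scenarios <- function(fit, scenario, data, level = 0.95) {
  vars <- all.vars(stats::formula(fit))[-1]
  nd <- as.data.frame(lapply(data[vars], mean))
  for (nm in names(scenario)) nd[[nm]] <- scenario[[nm]]
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (inherits(fit, "glm") && stats::family(fit)$family == "poisson") {
    pr <- stats::predict(fit, newdata = nd, type = "link", se.fit = TRUE)
    data.frame(fit = exp(pr$fit),
               lwr = exp(pr$fit - z * pr$se.fit),
               upr = exp(pr$fit + z * pr$se.fit))
  } else {
    pr <- stats::predict(fit, newdata = nd, se.fit = TRUE)
    data.frame(fit = pr$fit, lwr = pr$fit - z * pr$se.fit,
               upr = pr$fit + z * pr$se.fit)
  }
}
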