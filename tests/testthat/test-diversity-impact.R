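test_that("Shannon and Simpson match hand-computed values and invariances", {
  expect_equal(shannon_index(c(a = 7)), 0)
  expect_equal(simpson_index(c(a = 7)), 0)
  expect_equal(shannon_index(c(a = 4, b = 4)), log(2))
  expect_equal(simpson_index(c(a = 4, b = 4)), 0.5)
  counts <- c(a = 5, b = 3, c = 2)
  p <- counts / sum(counts)
  expect_equal(shannon_index(counts), -sum(p * log(p)))   # = 1.02965
  expect_equal(shannon_index(counts), 1.02965, tolerance = 1e-5)
  expect_equal(simpson_index(counts), 1 - sum(p^2))        # = 0.62
  expect_equal(shannon_index(numeric(0)), 0)
  expect_equal(simpson_index(c(a = 0, b = 0)), 0)

  # permutation- and scale-invariance
  set.seed(261)
  for (i in 1:10) {
    x <- rpois(6, 5) + 1
    names(x) <- letters[1:6]
    perm <- sample(x)
    expect_equal(shannon_index(x), shannon_index(perm))
    expect_equal(simpson_index(x), simpson_index(perm))
    expect_equal(shannon_index(x), shannon_index(x * 7))
    expect_equal(simpson_index(x), simpson_index(x * 7))
    expect_lte(shannon_index(x), log(sum(x > 0)) + 1e-12)
  }
})

test_that("per-site metrics exclude the invader and zero out empty sites", {
  counts <- rbind(c(2, 3, 50), c(0, 0, 10), c(1, 0, 0))
  colnames(counts) <- c("native_a", "native_b", "Trichonephila_clavata")
  dm <- diversity_metrics(counts)
  expect_equal(dm$richness, c(2, 0, 1))
  expect_equal(dm$shannon[2], 0)
  expect_equal(dm$simpson[2], 0)
  expect_equal(dm$shannon[1], shannon_index(c(2, 3)))
  with_inv <- diversity_metrics(counts, exclude_invader = FALSE)
  expect_equal(with_inv$richness, c(3, 1, 1))
})

test_that("survey summary reports occupancy percentages and mean abundances", {
  counts <- cbind(sp1 = c(3, 0, 1, 0), sp2 = c(1, 1, 1, 1))
  s <- summarize_surveys(counts)
  expect_equal(s$occupancy_pct[s$species == "sp1"], 50)
  expect_equal(s$occupancy_pct[s$species == "sp2"], 100)
  expect_equal(s$mean_per_site[s$species == "sp1"], 1)
  expect_equal(s$n_sites_present[s$species == "sp1"], 2)
  expect_equal(s$species[1], "sp2")   # sorted by occupancy
})

test_that("years-present follows the grid first-observation rule", {
  pt <- data.frame(lon = -83.8, lat = 34.1)
  occ <- function(date) data.frame(lon = -83.8005, lat = 34.1005,
                                   date = as.Date(date))
  as_of <- as.Date("2022-11-01")
  # first observation in the as-of year counts as one year
  expect_equal(years_present(occ("2022-06-15"), pt, as_of), 1L)
  # exactly three calendar years before
  expect_equal(years_present(occ("2019-11-01"), pt, as_of), 3L)
  # no record in the cell: zero
  far <- data.frame(lon = -80, lat = 30, date = as.Date("2019-01-01"))
  expect_equal(years_present(far, pt, as_of), 0L)
  # earliest record in the cell wins
  two <- rbind(occ("2018-05-01"), occ("2021-05-01"))
  expect_equal(years_present(two, pt, as_of), 4L)
})

test_that("Moran's I equals the brute-force double sum and flags degeneracies", {
  set.seed(271)
  coords <- data.frame(lon = runif(12, -84, -83), lat = runif(12, 34, 35))
  w <- neighbor_weights(coords, "knn", k = 2)
  vals <- rnorm(12)
  got <- morans_i(vals, w)
  z <- vals - mean(vals)
  n <- 12
  brute <- (n / sum(w)) * sum(outer(z, z) * w) / sum(z^2)
  expect_equal(got$I, brute, tolerance = 1e-10)
  # ape cross-check of the statistic and its null moments
  ref <- ape::Moran.I(vals, w)
  expect_equal(got$I, ref$observed, tolerance = 1e-10)
  expect_equal(got$expected, ref$expected, tolerance = 1e-10)
  expect_equal(got$sd, ref$sd, tolerance = 1e-10)

  expect_error(morans_i(rep(1, 12), w), "zero variance")

  # checkerboard on a rook-neighbor grid is negatively autocorrelated
  gr <- expand.grid(i = 0:3, j = 0:3)
  km <- 2 * pi * 6371.0088 / 360
  board <- data.frame(lon = gr$i * 5 / km, lat = gr$j * 5 / km)
  wb <- neighbor_weights(board, "radius", radius_km = 6)
  expect_lt(morans_i(rep_len(c(1, -1), 16) *
                       ifelse(gr$j %% 2 == 0, 1, -1), wb)$I, 0)
})

test_that("radius neighbors join isolated locations to their nearest neighbor", {
  coords <- data.frame(lon = c(0, 0.01, 0.02, 2), lat = c(0, 0, 0, 0))
  expect_message(w <- neighbor_weights(coords, "radius", radius_km = 10),
                 "isolated")
  expect_true(all(rowSums(w) > 0))
  expect_equal(which(w[4, ] > 0), 3L)   # joined to the nearest
})

test_that("AICc follows the small-sample formula with its boundary behavior", {
  # AIC = 100 with k = 3, n = 20 -> 100 + 24/16
  ll <- -(100 - 2 * 3) / 2
  expect_equal(aicc(ll, 3, 20), 101.5)
  expect_equal(aicc(ll, 3, 1e9), 100, tolerance = 1e-6)  # large-n limit: AIC
  expect_error(aicc(ll, 19, 20), "AICc undefined")
})

test_that("the model suite fits all structures and zeroes the best delta", {
  sv <- simulate_surveys(seed = 281)
  su <- fit_suite(sv)
  expect_equal(nrow(su), 12)
  for (resp in unique(su$response)) {
    expect_equal(min(su$delta_aicc[su$response == resp]), 0)
  }
  expect_true(all(is.na(su$interaction_coef[!su$interaction])))
  expect_true(all(!is.na(su$interaction_coef[su$interaction])))
  expect_true(all(su$family[su$response == "richness"] == "poisson"))
  models <- attr(su, "models")
  expect_s3_class(models$richness_years_present_interaction, "glm")
})

test_that("scenario prediction pins named covariates and respects coefficient signs", {
  # positive distance effect: diversity rises away from the centroid
  sp <- survey_spec(beta = list(temp = 0, wind = 0, rain = 0, jday = 0,
                                pop = -0.1, pred = 0.3, interaction = 0,
                                base_log_count = log(0.25)))
  sv <- simulate_surveys(sp, seed = 291, predictor = "distance_m")
  su <- fit_suite(sv, responses = "richness", predictors = "distance_m")
  fit <- attr(su, "models")$richness_distance_m_main
  stopifnot(coef(fit)["distance_m"] > 0)
  near <- predict_scenarios(fit, list(distance_m = 0), sv)
  far <- predict_scenarios(fit, list(distance_m = 1e5), sv)
  expect_gt(far$fit, near$fit)
  expect_true(near$lwr < near$fit && near$fit < near$upr)

  # Gaussian model at the covariate means reproduces the mean fitted value
  sug <- fit_suite(sv, responses = "shannon", predictors = "distance_m")
  lmfit <- attr(sug, "models")$shannon_distance_m_main
  at_means <- predict_scenarios(lmfit, list(), sv)
  expect_equal(at_means$fit, mean(fitted(lmfit)), tolerance = 1e-9)
})

test_that("null data give nominal interaction coverage and uniform Moran p-values", {
  set.seed(301)
  null_beta <- list(temp = 0, wind = 0, rain = 0, jday = 0, pop = 0,
                    pred = 0, interaction = 0, base_log_count = log(0.25))
  cover <- replicate(150, {
    sv <- simulate_surveys(survey_spec(beta = null_beta),
                           seed = sample.int(1e6, 1))
    su <- fit_suite(sv, responses = "shannon", predictors = "years_present")
    su$interaction_p[su$interaction] > 0.05
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)

  coords <- data.frame(lon = runif(40, -84, -83), lat = runif(40, 34, 35))
  w <- neighbor_weights(coords, "knn", k = 2)
  ps <- replicate(500, morans_i(rnorm(40), w)$p_value)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("interaction estimates are unbiased under the generative model", {
  set.seed(311)
  est <- replicate(150, {
    sv <- simulate_surveys(seed = sample.int(1e6, 1), mode = "direct")
    su <- fit_suite(sv, responses = "richness", predictors = "years_present")
    su$interaction_coef[su$interaction] *
      sd(sv$pop_density) * sd(sv$years_present)
  })
  truth <- survey_spec()$beta$interaction
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - truth), 3 * mc_se + 0.005)
})
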