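test_that("standardization centers, scales, stores invertible parameters", {
  tab <- data.frame(label = c("presence", "background", "presence"),
                    a = c(1, 2, 3), b = c(10, 30, 20))
  std <- standardize_predictors(tab)
  expect_equal(std$table$a, c(-1, 0, 1))
  expect_equal(mean(std$table$b), 0)
  expect_equal(sd(std$table$b), 1)
  # algebraic inverse round-trips
  p <- std$params
  back <- std$table$b * p$sd[p$predictor == "b"] + p$mean[p$predictor == "b"]
  expect_equal(back, tab$b, tolerance = 1e-12)
  tab$c <- 5
  expect_error(standardize_predictors(tab), "c")
})

test_that("rank AUC equals brute-force pairwise concordance", {
  set.seed(121)
  for (i in 1:10) {
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) y <- c(1, 0, y[-(1:2)])
    s <- sample(1:8, 20, replace = TRUE)  # heavy ties
    brute <- mean(outer(s[y == 1], s[y == 0], ">") +
                    0.5 * outer(s[y == 1], s[y == 0], "=="))
    expect_equal(auc_rank(s, y), brute, tolerance = 1e-12)
    expect_equal(auc_rank(s, y), as.numeric(suppressMessages(
      pROC::auc(y, s, direction = "<"))), tolerance = 1e-12)
  }
})

test_that("all four model kinds discriminate a strong synthetic landscape (CV AUC > 0.9)", {
  fx <- strong_sdm_table()
  folds <- local({set.seed(14); sample(rep(1:5, length.out = nrow(fx$std$table)))})
  for (k in c("glm", "gam", "maxent_like", "downsampled_rf")) {
    cv <- suppressWarnings(
      cross_validate(k, fx$std$table, folds, config = list(ntree = 300),
                     seed = 15))
    expect_gt(cv$mean_auc, 0.9)
    expect_lt(cv$mean_mae, 0.5)
  }
})

test_that("label permutation collapses discrimination to chance", {
  fx <- strong_sdm_table()
  tab <- fx$std$table
  set.seed(131)
  tab$label <- sample(tab$label)
  folds <- sample(rep(1:5, length.out = nrow(tab)))
  for (k in c("glm", "downsampled_rf")) {
    cv <- suppressWarnings(
      cross_validate(k, tab, folds, config = list(ntree = 300), seed = 16))
    expect_lt(abs(cv$mean_auc - 0.5), 0.05)
  }
})

test_that("spatial blocks partition points and co-block near neighbors", {
  set.seed(141)
  pts <- data.frame(lon = runif(500, -90, -70), lat = runif(500, 25, 45))
  folds <- assign_spatial_blocks(pts, block_size_km = 300, k = 10, seed = 17)
  expect_length(folds, 500)
  expect_true(all(folds %in% 1:10))
  expect_false(anyNA(folds))

  # two points ~10 km apart fall in one 860 km block, hence one fold
  near <- data.frame(lon = c(-83.0, -82.9, -60.0, -95, -83.5, -70, -88, -75,
                             -66, -92),
                     lat = c(34.0, 34.0, 50.0, 28, 40, 30, 44, 37, 26, 47))
  f <- assign_spatial_blocks(near, block_size_km = 860, k = 4, seed = 18)
  expect_equal(f[1], f[2])

  expect_error(assign_spatial_blocks(pts[1:3, ], block_size_km = 1e5, k = 10),
               "blocks")
})

test_that("cross-validation scores perfect separation as AUC 1 and skips one-class folds", {
  set.seed(151)
  n <- 200
  tab <- data.frame(label = rep(c("presence", "background"), each = n / 2),
                    x = c(rnorm(n / 2, 5), rnorm(n / 2, -5)))
  folds <- sample(rep(1:4, length.out = n))
  cv <- suppressWarnings(cross_validate("glm", tab, folds,
                                        config = list(min_presences = 10)))
  expect_true(all(cv$folds$auc == 1))

  lop <- c(rep(5L, 10), folds[-(1:10)])
  tab2 <- tab; tab2$label[1:10] <- "presence"
  expect_message(
    suppressWarnings(cross_validate("glm", tab2, lop,
                                    config = list(min_presences = 10))),
    "skipped")
})

test_that("block CV is no more optimistic than random CV under spatial autocorrelation", {
  diffs <- numeric(20)
  for (r in 1:20) {
    spec <- landscape_spec(
      ext = extent(100, 30, 108, 36), cellsize = 0.1,
      predictors = list(p1 = list(lengthscale = 25, variance = 1)),
      beta = list(intercept = -4, linear = c(p1 = 3), quadratic = c()))
    ls <- make_landscape(spec, seed = 200 + r)
    occ <- sample_presences(ls$truth, 300, seed = 300 + r)
    bg <- sample_background(ls$layers[[1]], 300, seed = 400 + r)
    pres <- extract_values(cbind(occ[c("lon", "lat")], label = "presence"),
                           ls$layers)
    bgx <- extract_values(bg, ls$layers)
    cols <- c("lon", "lat", "label", "p1")
    std <- standardize_predictors(rbind(pres[cols], bgx[cols]))
    blocked <- assign_spatial_blocks(std$table, block_size_km = 150, k = 5,
                                     seed = 500 + r)
    random <- local_seed_test(600 + r, sample(rep(1:5, length.out = nrow(std$table))))
    a_block <- suppressWarnings(
      cross_validate("glm", std$table, blocked))$mean_auc
    a_rand <- suppressWarnings(
      cross_validate("glm", std$table, random))$mean_auc
    diffs[r] <- a_rand - a_block
  }
  expect_gte(mean(diffs), 0)   # the designed pessimism of spatial blocking
})

test_that("maxent-like with linear features and no penalty matches the linear GLM ranking", {
  fx <- strong_sdm_table()
  tab <- fx$std$table
  m1 <- fit_sdm("maxent_like", tab,
                config = list(regmult = 0, feature_classes = "linear"))
  glm_lin <- suppressWarnings(
    glm(I(label == "presence") ~ temp_min + precip_season,
        family = binomial(), data = tab))
  p1 <- predict(m1, tab)
  p2 <- predict(glm_lin, type = "response")
  expect_gt(cor(p1, p2, method = "spearman"), 0.999)
})

test_that("GAM partial response is unimodal on a unimodal landscape", {
  hits <- 0
  for (r in 1:20) {
    spec <- landscape_spec(
      ext = extent(100, 30, 108, 36), cellsize = 0.1,
      predictors = list(env = list(lengthscale = 15, variance = 1)),
      beta = list(intercept = 0, linear = c(env = 0), quadratic = c(env = -2)))
    ls <- make_landscape(spec, seed = 700 + r)
    occ <- sample_presences(ls$truth, 400, seed = 800 + r)
    bg <- sample_background(ls$layers[[1]], 400, seed = 900 + r)
    pres <- extract_values(cbind(occ[c("lon", "lat")], label = "presence"),
                           ls$layers)
    bgx <- extract_values(bg, ls$layers)
    std <- standardize_predictors(rbind(pres[c("label", "env")],
                                        bgx[c("label", "env")]))
    m <- fit_sdm("gam", std$table)
    grid <- data.frame(env = seq(-2, 2, length.out = 41))
    resp <- predict(m, grid)
    peak <- which.max(resp)
    if (peak > 1 && peak < length(resp)) hits <- hits + 1
  }
  expect_gte(hits / 20, 0.9)
})

test_that("projection agrees with point-wise prediction and preserves bounds", {
  fx <- strong_sdm_table()
  std <- fx$std; ls <- fx$landscape
  m <- fit_sdm("glm", std$table)
  proj <- project_sdm(m, ls$layers, std$params)
  expect_true(all(proj$values >= 0 & proj$values <= 1, na.rm = TRUE))

  # cell-wise agreement with direct predict() on extracted values
  set.seed(161)
  rows <- sample(proj$nrow, 100, replace = TRUE)
  cols <- sample(proj$ncol, 100, replace = TRUE)
  ctr <- cell_center(proj, rows, cols)
  ext_vals <- extract_values(ctr, ls$layers)
  direct <- predict(m, apply_std_test(ext_vals, std$params))
  expect_equal(layer_value_at(proj, ctr$lon, ctr$lat), direct,
               tolerance = 1e-10)

  # constant rasters give constant suitability
  const <- lapply(ls$layers, function(l) {
    grid_layer(matrix(0.3, 5, 5), 0, 0, 1, name = l$name)
  })
  pc <- project_sdm(m, const, std$params)
  expect_equal(length(unique(as.vector(pc$values))), 1)

  expect_error(project_sdm(m, ls$layers["temp_min"], std$params), "missing")
})

test_that("model averaging is the cell-wise mean within [0, 1]", {
  vals <- c(0.2, 0.4, 0.6, 0.8)
  layers <- lapply(vals, function(v) toy_layer(matrix(v, 3, 3)))
  expect_true(all(average_models(layers)$values == 0.5))
  same <- lapply(1:4, function(i) toy_layer(matrix(0.37, 3, 3)))
  expect_true(all(average_models(same)$values == 0.37))

  set.seed(171)
  mats <- replicate(4, matrix(runif(25), 5, 5), simplify = FALSE)
  got <- average_models(lapply(mats, toy_layer))
  expect_equal(got$values, Reduce(`+`, mats) / 4, tolerance = 1e-12)
  expect_true(all(got$values >= 0 & got$values <= 1))
})
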