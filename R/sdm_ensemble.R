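#' Center and scale predictors, keeping the parameters
#'
#' Standardizes each predictor column to mean 0, sd 1 on the training table
#' and returns the means/sds so projection onto a new region can reuse the
#' training-time transform (never re-standardize on target-region values).
#'
#' @param table data.frame with numeric predictor columns; non-predictor
#'   columns `label`, `lon`, `lat` pass through untouched.
#' @return list with `table` (standardized) and `params` (data.frame
#'   `predictor`, `mean`, `sd`).
#' @export
standardize_predictors <- function(table) {
  preds <- setdiff(names(table), c("label", "lon", "lat"))
  stopifnot(length(preds) >= 1, nrow(table) >= 2)
  mu <- vapply(table[preds], mean, numeric(1))
  sd <- vapply(table[preds], stats::sd, numeric(1))
  if (any(sd == 0)) {
    stop("constant predictor column(s): ",
         paste(preds[sd == 0], collapse = ", "), call. = FALSE)
  }
  for (nm in preds) table[[nm]] <- (table[[nm]] - mu[nm]) / sd[nm]
  list(table = table,
       params = data.frame(predictor = preds, mean = unname(mu),
                           sd = unname(sd), stringsAsFactors = FALSE))
}

apply_standardization <- function(df, params) {
  for (i in seq_len(nrow(params))) {
    nm <- params$predictor[i]
    df[[nm]] <- (df[[nm]] - params$mean[i]) / params$sd[i]
  }
  df
}

# hinge feature basis: max(0, x - k) and max(0, k - x) at interior knots
hinge_basis <- function(x, knots) {
  out <- cbind(
    vapply(knots, function(k) pmax(0, x - k), numeric(length(x))),
    vapply(knots, function(k) pmax(0, k - x), numeric(length(x)))
  )
  colnames(out) <- c(paste0("hf", seq_along(knots)), paste0("hr", seq_along(knots)))
  out
}

maxent_features <- function(df, predictors, classes, knots) {
  blocks <- list(); pens <- numeric(0)
  for (nm in predictors) {
    x <- df[[nm]]
    if ("linear" %in% classes) {
      blocks[[paste0(nm, "_lin")]] <- matrix(x, ncol = 1)
      pens <- c(pens, 1)
    }
    if ("quadratic" %in% classes) {
      blocks[[paste0(nm, "_quad")]] <- matrix(x^2, ncol = 1)
      pens <- c(pens, 1)
    }
    if ("hinge" %in% classes) {
      hb <- hinge_basis(x, knots[[nm]])
      blocks[[paste0(nm, "_hinge")]] <- hb
      pens <- c(pens, rep(2, ncol(hb)))
    }
  }
  X <- do.call(cbind, blocks)
  colnames(X) <- unlist(lapply(names(blocks), function(b) {
    paste0(b, "_", seq_len(ncol(blocks[[b]]))) }))
  list(X = X, penalty = pens)
}

#' Fit a presence-background species distribution model
#'
#' Four model kinds, all exposing the same predict-probability contract
#' (suitability in `[0, 1]`):
#'
#' * `glm` — binomial regression with linear + quadratic terms per predictor.
#' * `gam` — binomial [mgcv::gam()] with a univariate penalized thin-plate
#'   smooth per predictor.
#' * `maxent_like` — penalized logistic regression of presence vs background
#'   on linear, quadratic and hinge feature expansions (the logistic
#'   equivalent of the maximum-entropy model on the same features): lasso
#'   penalty `regmult * sqrt(log(p)/n_presence)` with hinge features
#'   penalized twice as hard. `regmult = 0` with linear features only is an
#'   unpenalized logistic fit; `background_weight` optionally up-weights
#'   background rows (it shifts the intercept, not the suitability ranking).
#' * `downsampled_rf` — [randomForest::randomForest()] classification with
#'   `ntree` trees, per-tree stratified bootstrap drawing equal presence and
#'   background counts (down-sampling), and `sqrt(p)` candidate predictors
#'   per split.
#'
#' Predictors are assumed already standardized (see
#' [standardize_predictors()]).
#'
#' @param kind one of `"glm"`, `"gam"`, `"maxent_like"`, `"downsampled_rf"`.
#' @param table data.frame with `label` (`"presence"`/`"background"`) and
#'   standardized numeric predictor columns.
#' @param config list of options: `min_presences` (default 30), `ntree`
#'   (default 1000), `regmult` (default 1), `feature_classes` (default
#'   linear/quadratic/hinge), `n_hinge_knots` (default 5), `gam_k` (basis
#'   dimension, default 5).
#' @param seed integer seed (used by the random forest bootstrap).
#' @return an object of class `fitted_sdm` with a [predict()] method.
#' @export
fit_sdm <- function(kind = c("glm", "gam", "maxent_like", "downsampled_rf"),
                    table, config = list(), seed = 1L) {
  kind <- match.arg(kind)
  cfg <- utils::modifyList(list(min_presences = 30L, ntree = 1000L,
                                regmult = 1, n_hinge_knots = 5L, gam_k = 5L,
                                feature_classes = c("linear", "quadratic", "hinge"),
                                background_weight = 1),
                           config)
  y <- as.integer(table$label == "presence")
  if (!any(y == 1) || !any(y == 0)) {
    stop("both presence and background labels required", call. = FALSE)
  }
  if (sum(y) < cfg$min_presences) {
    stop("only ", sum(y), " presences; need at least ", cfg$min_presences,
         call. = FALSE)
  }
  predictors <- setdiff(names(table), c("label", "lon", "lat"))
  df <- table[predictors]
  fit <- switch(
    kind,
    glm = {
      rhs <- paste(
        vapply(predictors, function(p) sprintf("%s + I(%s^2)", p, p), ""),
        collapse = " + ")
      stats::glm(stats::as.formula(paste("y ~", rhs)),
                 family = stats::binomial(), data = cbind(df, y = y))
    },
    gam = {
      rhs <- paste(sprintf("s(%s, k = %d)", predictors, cfg$gam_k),
                   collapse = " + ")
      mgcv::gam(stats::as.formula(paste("y ~", rhs)),
                family = stats::binomial(), data = cbind(df, y = y),
                method = "REML")
    },
    maxent_like = {
      knots <- lapply(df, function(x) {
        stats::quantile(x, probs = seq_len(cfg$n_hinge_knots) /
                          (cfg$n_hinge_knots + 1), names = FALSE)
      })
      feats <- maxent_features(df, predictors, cfg$feature_classes, knots)
      w <- ifelse(y == 1, 1, cfg$background_weight)
      if (cfg$regmult == 0) {
        gf <- suppressWarnings(
          stats::glm.fit(cbind(1, feats$X), y, weights = w,
                         family = stats::binomial()))
        list(type = "glmfit", coef = gf$coefficients, knots = knots,
             classes = cfg$feature_classes)
      } else {
        lambda <- cfg$regmult * sqrt(log(ncol(feats$X)) / sum(y))
        gn <- glmnet::glmnet(feats$X, y, family = "binomial", weights = w,
                             alpha = 1, penalty.factor = feats$penalty,
                             lambda = c(lambda * 4, lambda * 2, lambda),
                             standardize = FALSE)
        list(type = "glmnet", fit = gn, lambda = lambda, knots = knots,
             classes = cfg$feature_classes)
      }
    },
    downsampled_rf = {
      yf <- factor(ifelse(y == 1, "presence", "background"),
                   levels = c("background", "presence"))
      per_class <- min(table(yf))   # equal counts per tree: the down-sampling
      local_seed(seed, randomForest::randomForest(
        x = df, y = yf, ntree = cfg$ntree,
        mtry = max(1L, floor(sqrt(length(predictors)))),
        strata = yf, sampsize = c(background = per_class, presence = per_class),
        replace = TRUE))
    }
  )
  structure(list(model_kind = kind, fit = fit, predictors = predictors,
                 config = cfg),
            class = "fitted_sdm")
}

#' Predict suitability from a fitted SDM
#'
#' @param object a `fitted_sdm`.
#' @param newdata data.frame containing the model's predictor columns,
#'   standardized with the training-time parameters.
#' @param ... ignored.
#' @return numeric vector of suitabilities in `[0, 1]` (`NA` where any
#'   predictor is `NA`).
#' @export
predict.fitted_sdm <- function(object, newdata, ...) {
  df <- newdata[object$predictors]
  ok <- stats::complete.cases(df)
  p <- rep(NA_real_, nrow(df))
  if (any(ok)) {
    sub <- df[ok, , drop = FALSE]
    p[ok] <- switch(
      object$model_kind,
      glm = stats::predict(object$fit, newdata = sub, type = "response"),
      gam = as.numeric(stats::predict(object$fit, newdata = sub,
                                      type = "response")),
      maxent_like = {
        feats <- maxent_features(sub, object$predictors, object$fit$classes,
                                 object$fit$knots)
        if (object$fit$type == "glmfit") {
          stats::plogis(drop(cbind(1, feats$X) %*% object$fit$coef))
        } else {
          as.numeric(stats::predict(object$fit$fit, newx = feats$X,
                                    s = object$fit$lambda,
                                    type = "response"))
        }
      },
      downsampled_rf = stats::predict(object$fit, newdata = sub,
                                      type = "prob")[, "presence"]
    )
  }
  pmin(1, pmax(0, p))
}

#' Assign spatial-block cross-validation folds
#'
#' Tiles the point extent with axis-aligned square blocks of the given edge
#' length (degrees converted to km at the dataset mid-latitude), then
#' assigns blocks to `k` folds at random (shuffled round-robin, so folds are
#' balanced in block count). All points in a block share a fold, which is
#' what prevents spatially autocorrelated test points from leaking training
#' information.
#'
#' @param points data.frame with `lon`, `lat`.
#' @param block_size_km block edge length in km (default 860, the study
#'   setting).
#' @param k number of folds (default 10).
#' @param seed integer seed for the block-to-fold assignment.
#' @return integer vector of fold ids (1..k), one per point.
#' @export
assign_spatial_blocks <- function(points, block_size_km = 860, k = 10L,
                                  seed = 1L) {
  stopifnot(block_size_km > 0, k >= 2)
  mid_lat <- mean(range(points$lat))
  x_km <- points$lon * KM_PER_DEG * cos(mid_lat * pi / 180)
  y_km <- points$lat * KM_PER_DEG
  bx <- floor((x_km - min(x_km)) / block_size_km)
  by <- floor((y_km - min(y_km)) / block_size_km)
  block <- paste(bx, by)
  blocks <- unique(block)
  if (length(blocks) < k) {
    stop("only ", length(blocks), " non-empty blocks for k = ", k,
         " folds; enlarge the extent or shrink the blocks", call. = FALSE)
  }
  fold_of <- local_seed(seed, {
    shuffled <- sample(blocks)
    stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)
  })
  unname(fold_of[block])
}

#' Area under the ROC curve by the rank statistic
#'
#' `AUC = (mean rank of presence scores - (n1 + 1)/2) / n0`, the
#' Mann-Whitney form; ties get midranks.
#'
#' @param scores numeric predictions.
#' @param labels 0/1 (1 = presence).
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (mean(r[labels == 1]) - (n1 + 1) / 2) / n0
}

#' Spatial-block cross-validation of an SDM
#'
#' Per fold: train on the out-of-fold rows, predict the held-out rows, score
#' AUC (rank statistic, presence vs background) and MAE
#' (`mean |label - probability|`, labels 1/0). Folds with a single class are
#' skipped with a message.
#'
#' @param kind model kind, as [fit_sdm()].
#' @param table labelled standardized training table.
#' @param folds integer fold ids from [assign_spatial_blocks()] (or any
#'   partition).
#' @param config,seed passed to [fit_sdm()].
#' @return list with `folds` (data.frame `fold_id`, `auc`, `mae`),
#'   `mean_auc`, `mean_mae`.
#' @export
cross_validate <- function(kind, table, folds, config = list(), seed = 1L) {
  stopifnot(nrow(table) == length(folds))
  rows <- list()
  for (f in sort(unique(folds))) {
    test <- table[folds == f, , drop = FALSE]
    train <- table[folds != f, , drop = FALSE]
    y_test <- as.integer(test$label == "presence")
    if (length(unique(y_test)) < 2 ||
        length(unique(train$label)) < 2) {
      message("fold ", f, " skipped (single class)")
      next
    }
    model <- fit_sdm(kind, train, config = config, seed = seed)
    p <- predict(model, test)
    rows[[length(rows) + 1L]] <- data.frame(
      fold_id = f, auc = auc_rank(p, y_test), mae = mean(abs(y_test - p)))
  }
  res <- do.call(rbind, rows)
  list(folds = res, mean_auc = mean(res$auc), mean_mae = mean(res$mae))
}

#' Project a fitted SDM onto raster layers
#'
#' Applies the training-time standardization to the target-region predictor
#' values, predicts every cell, and returns a suitability raster in
#' `[0, 1]`. Nodata in any predictor layer propagates.
#'
#' @param model a `fitted_sdm`.
#' @param layers named list of co-registered [grid_layer()]s covering every
#'   predictor the model uses.
#' @param params standardization parameters from [standardize_predictors()].
#' @return a `grid_layer` of suitabilities.
#' @export
project_sdm <- function(model, layers, params) {
  nms <- names(layers)
  missing <- setdiff(model$predictors, nms)
  if (length(missing)) {
    stop("layers missing predictors: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tmpl <- layers[[1]]
  df <- as.data.frame(lapply(layers[model$predictors], function(l) {
    as.vector(t(l$values))       # row-major: matches cell index order
  }))
  names(df) <- model$predictors
  df <- apply_standardization(df, params[params$predictor %in% model$predictors, ])
  p <- predict(model, df)
  grid_layer(matrix(p, nrow = tmpl$nrow, ncol = tmpl$ncol, byrow = TRUE),
             tmpl$xmin, tmpl$ymin, tmpl$cellsize,
             name = paste0("suitability_", model$model_kind))
}

#' Equally weighted ensemble of suitability rasters
#'
#' Cell-wise arithmetic mean of the four model projections; nodata in any
#' input propagates. Preserves the `[0, 1]` bounds.
#'
#' @param rasters list of co-registered suitability `grid_layer`s.
#' @return a `grid_layer`.
#' @export
average_models <- function(rasters) {
  out <- average_layers(rasters, name = "suitability_ensemble")
  rng <- range(out$values, na.rm = TRUE)
  if (length(rasters) && (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)) {
    stop("inputs are not suitability rasters in [0, 1]", call. = FALSE)
  }
  out
}
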