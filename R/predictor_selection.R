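#' Mann-Whitney U test with rank-biserial effect size
#'
#' Compares a climate variable between two regions (e.g. native vs introduced
#' range) with the Mann-Whitney U statistic (midrank tie correction), a
#' two-sided normal-approximation p-value with tie-corrected variance, and
#' the rank-biserial correlation `r_rb = 1 - 2U/(n_x n_y)` where `U` counts
#' wins of `x` over `y` (ties count one half). `r_rb = 1` means every `x` is
#' below every `y`.
#'
#' Effect classes follow common usage: large if `|r_rb| > .5`, moderate if
#' `.3 < |r_rb| <= .5`, else small.
#'
#' @param x,y numeric samples (non-empty).
#' @param name variable name carried into the result.
#' @return data.frame with `name`, `u_statistic`, `p_value`, `r_rb`,
#'   `effect_class`.
#' @export
mann_whitney_rankbiserial <- function(x, y, name = "predictor") {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2   # wins of x (ties = 1/2)
  n <- nx + ny
  ties <- table(c(x, y))
  tie_term <- sum(ties^3 - ties)
  v <- nx * ny / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (v > 0) (u - nx * ny / 2) / sqrt(v) else 0
  p <- if (v > 0) 2 * stats::pnorm(-abs(z)) else 1
  r_rb <- 1 - 2 * u / (nx * ny)
  cls <- if (abs(r_rb) > 0.5) "large" else if (abs(r_rb) > 0.3) "moderate" else "small"
  data.frame(name = name, u_statistic = u, p_value = p, r_rb = r_rb,
             effect_class = cls, stringsAsFactors = FALSE)
}

#' Compare every predictor between two labelled regions
#'
#' @param values data.frame of predictor columns.
#' @param region factor/character vector with exactly two levels; the first
#'   level plays the role of `x`.
#' @return data.frame, one [mann_whitney_rankbiserial()] row per predictor.
#' @export
compare_climates <- function(values, region) {
  lv <- unique(as.character(region))
  stopifnot(length(lv) == 2)
  do.call(rbind, lapply(names(values), function(nm) {
    mann_whitney_rankbiserial(values[[nm]][region == lv[1]],
                              values[[nm]][region == lv[2]], name = nm)
  }))
}

#' Rank predictors by bivariate logistic regression
#'
#' Fits one single-predictor binomial GLM (intercept + slope) per predictor
#' on standardized values and ranks predictors by descending `|slope|`
#' (equivalently `|log odds ratio|`). Complete separation yields a huge
#' fitted slope and hence a top rank (flagged); a fit that errors out is
#' assigned the worst rank and flagged. Ties break by column order.
#'
#' @param samples data.frame with a `label` column (`"presence"` /
#'   `"background"`) and numeric predictor columns.
#' @return data.frame `name`, `odds_ratio`, `rank`, `flagged`, ordered by
#'   rank.
#' @export
rank_predictors <- function(samples) {
  stopifnot("label" %in% names(samples))
  y <- as.integer(samples$label == "presence")
  if (!any(y == 1) || !any(y == 0)) {
    stop("both presence and background labels required", call. = FALSE)
  }
  preds <- setdiff(names(samples), c("label", "lon", "lat"))
  fits <- lapply(preds, function(nm) {
    x <- as.numeric(scale(samples[[nm]]))
    out <- tryCatch({
      fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
      list(slope = unname(stats::coef(fit)[2]),
           flagged = !fit$converged || abs(unname(stats::coef(fit)[2])) > 15)
    }, error = function(e) list(slope = NA_real_, flagged = TRUE))
    out
  })
  slope <- vapply(fits, `[[`, numeric(1), "slope")
  flagged <- vapply(fits, `[[`, logical(1), "flagged")
  key <- abs(slope)
  key[is.na(key)] <- -Inf                      # failed fits sort last
  ord <- order(-key, seq_along(preds))         # ties: earlier column wins
  res <- data.frame(name = preds[ord], odds_ratio = exp(slope[ord]),
                    rank = seq_along(preds), flagged = flagged[ord],
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Reduce predictors by iterative removal from correlated pairs
#'
#' Implements the reduction loop: compute all pairwise Pearson correlations
#' among surviving predictors; while any pair has `|r|` above the threshold,
#' remove the single worst-ranked predictor participating in at least one
#' such pair, then recompute. The absolute value of `r` is used — a strong
#' negative correlation is just as redundant as a positive one.
#'
#' @param ranks data.frame from [rank_predictors()] (`name`, `rank`).
#' @param values data.frame of predictor columns covering every ranked name.
#' @param r_threshold correlation threshold (default 0.7).
#' @return character vector of surviving predictor names in rank order.
#' @export
reduce_predictors <- function(ranks, values, r_threshold = 0.7) {
  stopifnot(all(ranks$name %in% names(values)))
  alive <- ranks$name[order(ranks$rank)]
  repeat {
    if (length(alive) < 2) break
    cm <- abs(stats::cor(values[alive]))
    diag(cm) <- 0
    if (max(cm) <= r_threshold) break
    involved <- alive[apply(cm > r_threshold, 1, any)]
    worst <- involved[length(involved)]        # alive is rank-ordered
    alive <- setdiff(alive, worst)
  }
  alive
}

#' Correlated predictor pairs
#'
#' @param values data.frame of predictor columns.
#' @param r_threshold report pairs with `|r|` above this.
#' @return data.frame `a`, `b`, `r`.
#' @export
correlated_pairs <- function(values, r_threshold = 0.7) {
  cm <- stats::cor(values)
  idx <- which(upper.tri(cm) & abs(cm) > r_threshold, arr.ind = TRUE)
  data.frame(a = rownames(cm)[idx[, 1]], b = colnames(cm)[idx[, 2]],
             r = cm[idx], stringsAsFactors = FALSE)
}

#' Cell-wise maximum wind speed across monthly layers
#'
#' Collapses the 12 monthly wind-speed rasters into a single
#' maximum-wind-speed predictor. Nodata in any month propagates.
#'
#' @param monthly_wind list of 12 co-registered [grid_layer()]s.
#' @return a `grid_layer` named `"wind_max"`.
#' @export
max_wind_speed <- function(monthly_wind) {
  stopifnot(length(monthly_wind) == 12)
  for (l in monthly_wind[-1]) {
    if (!same_geometry(monthly_wind[[1]], l)) {
      stop("monthly layers are not co-registered", call. = FALSE)
    }
  }
  vals <- lapply(monthly_wind, `[[`, "values")
  out <- Reduce(function(a, b) {
    r <- pmax(a, b)
    r[is.na(a) | is.na(b)] <- NA_real_
    r
  }, vals)
  grid_layer(out, monthly_wind[[1]]$xmin, monthly_wind[[1]]$ymin,
             monthly_wind[[1]]$cellsize, name = "wind_max")
}
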