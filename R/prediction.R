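## Phylogeny-aware prediction intervals around a PGLS fit, and outlier
## flagging of species relative to the band.

#' Phylogeny-aware prediction band around a PGLS fit
#'
#' At each predictor value x0 the band is
#' `yhat0 +/- t(level, df) * sqrt(s2 * (v00 - v0' V^-1 v0) + var(yhat0))`,
#' where `v00` is the hypothetical new species' own phylogenetic variance
#' and `v0` its covariance with the sampled species. The default
#' convention — `v0 = 0` and `v00 =` tree height — treats the new species
#' as an unrelated tip of root-to-tip depth equal to the tree's, which is
#' the single global band a scatterplot draws for all species at once. For
#' a species with a known position in the tree, pass its covariance vector
#' (ordered as `fit$species`) via `target_covariance`, optionally with its
#' own depth via `target_variance`; the predicted mean then includes the
#' BLUP adjustment `v0' V^-1 (y - X beta)`.
#'
#' On a star phylogeny with `lambda = 0` the default band reduces to the
#' textbook OLS prediction interval. Quantiles are Student-t with the
#' fit's residual degrees of freedom.
#'
#' @param fit A [fit_pgls()] result.
#' @param x_grid Predictor grid on the log10 scale; default 100 points
#'   spanning the observed range.
#' @param level Coverage level in (0, 1); default 0.95.
#' @param target_covariance Optional numeric vector of phylogenetic
#'   covariances between the new species and each sampled species, in
#'   `fit$species` order.
#' @param target_variance Optional own variance of the new species;
#'   defaults to the tree height.
#' @return A `prediction_band`: a data frame with columns `x`, `fit`,
#'   `lwr`, `upr` and attributes `level` and `fit`.
#' @export
prediction_band <- function(fit, x_grid = NULL, level = 0.95,
                            target_covariance = NULL, target_variance = NULL) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (fit$residual_df < 2L) stop("fit has fewer than 2 residual df", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1) {
    stop("level must be a single value in (0, 1)", call. = FALSE)
  }
  if (is.null(x_grid)) {
    x_grid <- seq(min(fit$x), max(fit$x), length.out = 100L)
  }
  pv <- predictive_moments(fit, x_grid, target_covariance, target_variance)
  tq <- stats::qt(1 - (1 - level) / 2, fit$residual_df)
  out <- data.frame(x = x_grid, fit = pv$mean,
                    lwr = pv$mean - tq * pv$se, upr = pv$mean + tq * pv$se)
  structure(out, level = level, fit = fit,
            target_covariance = target_covariance,
            target_variance = target_variance,
            class = c("prediction_band", "data.frame"))
}

## Predictive mean and standard error at each x0, shared by band and flags.
predictive_moments <- function(fit, x0, v0 = NULL, v00 = NULL) {
  n <- fit$n
  R <- fit$chol_V
  X <- cbind(1, fit$x)
  if (is.null(v00)) v00 <- fit$tree_height
  if (!is.null(v0)) {
    if (length(v0) != n) {
      stop("target_covariance must have length ", n,
           " (one entry per sampled species)", call. = FALSE)
    }
    # whitened forms: V^-1 a = R^-1 (R^-T a)
    wv <- backsolve(R, v0, transpose = TRUE)
    wr <- backsolve(R, fit$y - fit$fitted, transpose = TRUE)
    wX <- backsolve(R, X, transpose = TRUE)
    blup <- sum(wv * wr)
    shrink <- sum(wv * wv)
    dX <- drop(crossprod(wX, wv))      # X' V^-1 v0
  } else {
    blup <- 0
    shrink <- 0
    dX <- c(0, 0)
  }
  s2 <- fit$sigma2
  Cinv <- fit$coef_vcov / s2           # (X' V^-1 X)^-1
  mean <- fit$intercept + fit$slope * x0 + blup
  var <- vapply(x0, function(xi) {
    d <- c(1, xi) - dX
    s2 * (v00 - shrink) + s2 * drop(t(d) %*% Cinv %*% d)
  }, numeric(1))
  if (any(var < 0)) var <- pmax(var, 0)
  list(mean = mean, se = sqrt(var))
}

#' Flag species lying outside a prediction band
#'
#' Recomputes the band bounds exactly at each sampled species' predictor
#' value (so species outside the plotted grid are still assessed; a notice
#' is emitted when the grid had to be exceeded) and marks each species as
#' inside, above or below. The signed deviation is the residual from the
#' fitted line in units of the band half-width at that point.
#'
#' @param fit A [fit_pgls()] result.
#' @param band A [prediction_band()] for `fit`; its level and new-species
#'   convention are reused. Defaults to the 95% global band.
#' @return A data frame with one row per species: `species`, `x`
#'   (log10 predictor), `observed`, `predicted`, `lwr`, `upr`, `status`
#'   (`"inside"`, `"above"`, `"below"`) and `deviation`.
#' @export
flag_outliers <- function(fit, band = NULL) {
  stopifnot(inherits(fit, "pgls_fit"))
  if (is.null(band)) band <- prediction_band(fit)
  stopifnot(inherits(band, "prediction_band"))
  level <- attr(band, "level")
  if (any(fit$x < min(band$x) | fit$x > max(band$x))) {
    message("some species lie outside the band grid; bounds recomputed at ",
            "their exact predictor values")
  }
  pv <- predictive_moments(fit, fit$x, attr(band, "target_covariance"),
                           attr(band, "target_variance"))
  tq <- stats::qt(1 - (1 - level) / 2, fit$residual_df)
  lwr <- pv$mean - tq * pv$se
  upr <- pv$mean + tq * pv$se
  status <- ifelse(fit$y > upr, "above", ifelse(fit$y < lwr, "below", "inside"))
  data.frame(
    species = fit$species,
    x = fit$x,
    observed = fit$y,
    predicted = pv$mean,
    lwr = lwr,
    upr = upr,
    status = status,
    deviation = (fit$y - pv$mean) / (tq * pv$se),
    row.names = NULL
  )
}
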