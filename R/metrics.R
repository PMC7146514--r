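#' Coefficient of determination (squared Pearson correlation)
#'
#' Chemometric convention: \eqn{R^2 = cor(obs, pred)^2}, affine-invariant and
#' symmetric in its arguments. A constant prediction vector returns 0 with a
#' warning. The residual-based \eqn{1 - SS_{res}/SS_{tot}} variant is
#' available as [r_squared_ss()].
#'
#' @param obs Observed values (non-constant, n >= 3).
#' @param pred Predicted values, same length.
#' @return R-squared in [0, 1].
#' @export
r_squared <- function(obs, pred) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (length(obs) != length(pred)) stop("length mismatch")
  if (length(obs) < 3L) stop("need at least 3 observations")
  if (stats::sd(obs) < 1e-12) stop("constant observations")
  if (stats::sd(pred) < 1e-12) {
    warning("constant predictions: R2 reported as 0")
    return(0)
  }
  stats::cor(obs, pred)^2
}

#' Residual-based coefficient of determination
#'
#' \eqn{1 - \sum (obs - pred)^2 / \sum (obs - \bar{obs})^2}; can be negative
#' for predictions worse than the mean.
#'
#' @inheritParams r_squared
#' @return Numeric scalar (at most 1).
#' @export
r_squared_ss <- function(obs, pred) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (length(obs) != length(pred)) stop("length mismatch")
  sst <- sum((obs - mean(obs))^2)
  if (sst <= 0) stop("constant observations")
  1 - sum((obs - pred)^2) / sst
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the units of \code{obs} (g/kg for SOM).
#' @export
rmse <- function(obs, pred) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (length(obs) == 0L) stop("empty input")
  if (length(obs) != length(pred)) stop("length mismatch")
  sqrt(mean((obs - pred)^2))
}

#' Ratio of performance to interquartile distance (RPIQ)
#'
#' \code{RPIQ = IQR(observed validation values) / validation RMSE}, with the
#' IQR computed by linear-interpolation quantiles (R type 7). Higher is
#' better; being IQR-based it is robust to the skewed SOM distributions
#' typical of arid soils.
#'
#' @param obs_val Observed validation values (n >= 4), or a single
#'   pre-computed IQR value if \code{is_iqr = TRUE}.
#' @param rmse_val Validation RMSE (> 0).
#' @param is_iqr Set to TRUE when \code{obs_val} is already an IQR.
#' @return RPIQ (dimensionless, > 0).
#' @export
rpiq <- function(obs_val, rmse_val, is_iqr = FALSE) {
  if (!is.finite(rmse_val) || rmse_val <= 0) stop("rmse_val must be > 0")
  iqr <- if (is_iqr) {
    as.numeric(obs_val)
  } else {
    obs_val <- as.numeric(obs_val)
    if (length(obs_val) < 4L) stop("need at least 4 validation observations")
    q <- stats::quantile(obs_val, c(0.25, 0.75), type = 7, names = FALSE)
    q[2] - q[1]
  }
  iqr / rmse_val
}

#' RPIQ quality category
#'
#' A: RPIQ > 4.05 (excellent); B: 3.37 < RPIQ <= 4.05 (good);
#' C: 2.70 < RPIQ <= 3.37 (limited); D: RPIQ <= 2.70 (poor). Boundary points
#' are closed upward into the lower category (4.05 -> B, 3.37 -> C,
#' 2.70 -> D).
#'
#' @param x RPIQ value (> 0).
#' @return One of \code{"A"}, \code{"B"}, \code{"C"}, \code{"D"}.
#' @export
rpiq_category <- function(x) {
  if (!is.finite(x) || x <= 0) stop("RPIQ must be positive")
  if (x > 4.05) "A" else if (x > 3.37) "B" else if (x > 2.70) "C" else "D"
}

#' Confidence and prediction bands for a measured-vs-predicted fit
#'
#' OLS fit of predictions on observations with pointwise \code{1 - alpha}
#' confidence band for the mean response and prediction band for new
#' observations, as drawn on 1:1 scatter plots. The prediction band strictly
#' contains the confidence band at every point.
#'
#' @param obs Observed values (non-constant, n >= 3).
#' @param pred Predicted values, same length.
#' @param alpha Significance level (default 0.05 for 95% bands).
#' @param newdata Optional observation values at which to evaluate the bands
#'   (default: the sorted observations).
#' @return data.frame: \code{obs}, \code{fit}, \code{ci_lo}, \code{ci_hi},
#'   \code{pi_lo}, \code{pi_hi}.
#' @export
interval_bands <- function(obs, pred, alpha = 0.05, newdata = NULL) {
  obs <- as.numeric(obs); pred <- as.numeric(pred)
  if (length(obs) != length(pred)) stop("length mismatch")
  if (length(obs) < 3L) stop("need at least 3 observations")
  if (stats::sd(obs) < 1e-12) stop("constant observations")
  df <- data.frame(obs = obs, pred = pred)
  fit <- stats::lm(pred ~ obs, data = df)
  if (is.null(newdata)) newdata <- sort(obs)
  nd <- data.frame(obs = as.numeric(newdata))
  ci <- stats::predict(fit, nd, interval = "confidence", level = 1 - alpha)
  pi <- stats::predict(fit, nd, interval = "prediction", level = 1 - alpha)
  data.frame(obs = nd$obs, fit = ci[, "fit"],
             ci_lo = ci[, "lwr"], ci_hi = ci[, "upr"],
             pi_lo = pi[, "lwr"], pi_hi = pi[, "upr"])
}

#' ANOVA stability check between calibration and validation metrics
#'
#' One-way ANOVA comparing per-model calibration metrics against validation
#' metrics (e.g. the six R2 or RMSE values of the strategy table); p > 0.05
#' indicates no significant difference, i.e. stable models. Delegates to
#' [anova_p()].
#'
#' @param metric_cal,metric_val Numeric vectors of per-model metric values.
#' @return p-value in [0, 1].
#' @export
stability_anova <- function(metric_cal, metric_val) {
  anova_p(metric_cal, metric_val)
}

#' Bundle calibration/validation accuracy metrics
#'
#' @param cal_obs,cal_pred Calibration observed/predicted SOM.
#' @param val_obs,val_pred Validation observed/predicted SOM.
#' @return List of class \code{som_metrics}: \code{r2_cal}, \code{rmse_cal},
#'   \code{r2_val}, \code{rmse_val}, \code{rpiq}, \code{category}.
#' @export
evaluate_predictions <- function(cal_obs, cal_pred, val_obs, val_pred) {
  rmse_val <- rmse(val_obs, val_pred)
  rp <- rpiq(val_obs, rmse_val)
  structure(
    list(r2_cal = r_squared(cal_obs, cal_pred),
         rmse_cal = rmse(cal_obs, cal_pred),
         r2_val = r_squared(val_obs, val_pred),
         rmse_val = rmse_val,
         rpiq = rp,
         category = rpiq_category(rp)),
    class = "som_metrics"
  )
}

#' @export
print.som_metrics <- function(x, ...) {
  cat(sprintf(
    "R2c %.2f RMSEc %.2f | R2v %.2f RMSEv %.2f | RPIQ %.2f (%s)\n",
    x$r2_cal, x$rmse_cal, x$r2_val, x$rmse_val, x$rpiq, x$category))
  invisible(x)
}
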