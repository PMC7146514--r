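#' Ordinary least-squares single-variable fit
#'
#' Fits \code{y = intercept + slope * x} (the single-index linear models of
#' the strategy comparison).
#'
#' @param x Feature vector (non-constant, n >= 3).
#' @param y SOM vector, same length.
#' @return List of class \code{linear_fit}: \code{slope}, \code{intercept},
#'   \code{fitted}, and a \code{predict(newx)} closure.
#' @export
fit_linear <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 points")
  if (stats::sd(x) < 1e-12) stop("constant x: slope undefined")
  fit <- stats::lm(y ~ x, data = data.frame(x = x, y = y))
  co <- stats::coef(fit)
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]),
         fitted = unname(stats::fitted(fit)),
         predict = function(newx) unname(co[1] + co[2] * as.numeric(newx))),
    class = "linear_fit"
  )
}

rf_oob_rmse <- function(model, y) {
  sqrt(mean((model$predicted - y)^2))
}

candidate_seed <- function(seed, m) as.integer(seed) + as.integer(m)

#' Tune the random-forest mtry hyperparameter
#'
#' Fits one seeded forest per candidate \code{mtry} and scores it by
#' out-of-bag RMSE on the calibration set; returns the candidate minimizing
#' it (ties go to the smaller mtry). OOB RMSE is the standard unbiased
#' in-sample proxy; resubstitution RMSE would be nearly monotone in mtry and
#' make the tuning vacuous. Each candidate fit uses the deterministic seed
#' \code{seed + mtry}, so any single candidate can be refit reproducibly.
#'
#' @param X Calibration feature matrix (samples x features).
#' @param y Calibration SOM vector.
#' @param mtry_range Integer candidates, all within \code{[1, ncol(X)]}.
#' @param n_trees Number of trees.
#' @param nodesize Minimum terminal node size (regression default 5).
#' @param seed Base seed.
#' @return List: \code{best_mtry}, \code{oob_rmse} (named by mtry).
#' @export
tune_mtry <- function(X, y, mtry_range, n_trees = 1000, nodesize = 5, seed = 1L) {
  X <- as.matrix(X)
  mtry_range <- as.integer(mtry_range)
  if (length(mtry_range) == 0L) stop("empty mtry range")
  if (any(mtry_range < 1L) || any(mtry_range > ncol(X))) {
    stop("mtry_range must lie within [1, n_features]")
  }
  oob <- vapply(mtry_range, function(m) {
    with_seed(candidate_seed(seed, m), {
      fit <- randomForest::randomForest(x = X, y = y, ntree = n_trees,
                                        mtry = m, nodesize = nodesize)
      rf_oob_rmse(fit, y)
    })
  }, numeric(1))
  names(oob) <- mtry_range
  best <- mtry_range[which.min(oob)]  # which.min: first minimum -> smaller mtry
  list(best_mtry = best, oob_rmse = oob)
}

#' Fit a seeded random-forest regression
#'
#' Bagged regression-tree ensemble; predictions are averages of leaf means,
#' hence bounded by the calibration SOM range. Identical seeds give
#' identical forests.
#'
#' @param X Feature matrix (n >= 10 samples).
#' @param y Response vector (SOM g/kg).
#' @param n_trees Number of trees (study setting: 1000).
#' @param m_try Candidate features per split, \code{<= ncol(X)}.
#' @param nodesize Minimum terminal node size.
#' @param seed Seed for the fit.
#' @return List of class \code{rf_fit}: the \code{model}, \code{oob_rmse},
#'   raw \code{importance} (variance-reduction), and a
#'   \code{predict(newX)} closure.
#' @export
fit_rf <- function(X, y, n_trees = 1000, m_try, nodesize = 5, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 10L) stop("need at least 10 samples")
  if (m_try > ncol(X)) stop("m_try exceeds the number of features")
  model <- with_seed(seed, {
    randomForest::randomForest(x = X, y = as.numeric(y), ntree = n_trees,
                               mtry = m_try, nodesize = nodesize,
                               importance = FALSE)
  })
  structure(
    list(model = model,
         oob_rmse = rf_oob_rmse(model, as.numeric(y)),
         importance = stats::setNames(as.numeric(model$importance[, 1]),
                                      rownames(model$importance)),
         predict = function(newX) {
           unname(stats::predict(model, as.matrix(newX)))
         }),
    class = "rf_fit"
  )
}

#' Normalize raw importances to percentages
#'
#' @param raw Non-negative raw importance vector, not all zero.
#' @return Percentages summing to 100, names preserved.
#' @export
normalize_importance <- function(raw) {
  raw <- unlist(raw)
  if (any(raw < 0)) stop("raw importances must be >= 0")
  s <- sum(raw)
  if (s <= 0) stop("all-zero importances cannot be normalized")
  100 * raw / s
}

#' Build the six feature-set strategies
#'
#' Assembles calibration and validation design matrices for the strategies
#' 1DV (5 PCA scores), 2DI (5 two-band indices), 3DI (5 three-band indices)
#' and their pairwise unions (10 features each). The PCA is fitted on the
#' calibration continuum-removed spectra only; validation scores are
#' projected. Index features are evaluated from the selected band
#' combinations on the smoothed spectra.
#'
#' @param cal,val [soil_dataset]s on the preprocessed (smoothed) grid.
#' @param selected Selection table from [search_indices()] covering the five
#'   two-band and five three-band forms.
#' @param cal_cr,val_cr Continuum-removed [spectra_set]s for the PCA features
#'   (same grid).
#' @return List of class \code{feature_sets}: per strategy, a list with
#'   \code{cal} and \code{val} matrices sharing column names.
#' @export
build_feature_sets <- function(cal, val, selected, cal_cr, val_cr) {
  pca <- fit_pca(cal_cr, min_components = 5L)
  k <- min(5L, pca$n_retained)
  dv_cal <- pca$scores[, seq_len(k), drop = FALSE]
  dv_val <- project_pca(pca, val_cr)[, seq_len(k), drop = FALSE]

  feat <- function(ds, rows) {
    cols <- lapply(seq_len(nrow(rows)), function(i) {
      bands <- c(rows$wl_i[i], rows$wl_j[i], rows$wl_k[i])
      bands <- bands[!is.na(bands)]
      index_values(as.character(rows$form[i]), ds$spectra, bands)
    })
    m <- do.call(cbind, cols)
    colnames(m) <- as.character(rows$form)
    m
  }
  two <- selected[selected$form %in% TWO_BAND_FORMS, , drop = FALSE]
  three <- selected[selected$form %in% THREE_BAND_FORMS, , drop = FALSE]
  if (nrow(two) != 5L || nrow(three) != 5L) {
    stop("selection table must cover all five two-band and five three-band forms")
  }
  di2_cal <- feat(cal, two); di2_val <- feat(val, two)
  di3_cal <- feat(cal, three); di3_val <- feat(val, three)

  fs <- list(
    "1DV" = list(cal = dv_cal, val = dv_val),
    "2DI" = list(cal = di2_cal, val = di2_val),
    "3DI" = list(cal = di3_cal, val = di3_val),
    "1DV+2DI" = list(cal = cbind(dv_cal, di2_cal), val = cbind(dv_val, di2_val)),
    "1DV+3DI" = list(cal = cbind(dv_cal, di3_cal), val = cbind(dv_val, di3_val)),
    "2DI+3DI" = list(cal = cbind(di2_cal, di3_cal),
                     val = cbind(di2_val, di3_val))
  )
  for (nm in names(fs)) {
    if (any(!is.finite(fs[[nm]]$cal)) || any(!is.finite(fs[[nm]]$val))) {
      stop("non-finite feature values in strategy ", nm)
    }
  }
  structure(fs, class = "feature_sets")
}

#' Fit random forests for all six variable strategies
#'
#' For each strategy, tunes mtry over 1..5 (single-dimension strategies) or
#' 1..10 (pairwise combinations) by out-of-bag RMSE, fits the final seeded
#' forest, and evaluates calibration and validation predictions with R2,
#' RMSE and RPIQ (plus its A-D category). Variable importances are
#' normalized to a 100% scale.
#'
#' @param features A [build_feature_sets()] result.
#' @param cal_som,val_som Calibration and validation SOM vectors.
#' @param n_trees Trees per forest (study setting: 1000).
#' @param nodesize Minimum terminal node size.
#' @param seed Base seed; strategies use deterministic offsets of it.
#' @return List of class \code{strategy_results}, one element per strategy:
#'   \code{strategy}, \code{m_try}, \code{oob_rmse}, \code{metrics} (from
#'   [evaluate_predictions()]), \code{predictions}, \code{importance}.
#' @export
run_all_strategies <- function(features, cal_som, val_som, n_trees = 1000,
                               nodesize = 5, seed = 1L) {
  stopifnot(inherits(features, "feature_sets"))
  out <- vector("list", length(features))
  names(out) <- names(features)
  for (s in seq_along(features)) {
    nm <- names(features)[s]
    Xc <- features[[s]]$cal
    Xv <- features[[s]]$val
    rng <- seq_len(min(if (grepl("+", nm, fixed = TRUE)) 10L else 5L, ncol(Xc)))
    strat_seed <- as.integer(seed) + 100L * s
    tuned <- tune_mtry(Xc, cal_som, rng, n_trees = n_trees,
                       nodesize = nodesize, seed = strat_seed)
    fit <- fit_rf(Xc, cal_som, n_trees = n_trees, m_try = tuned$best_mtry,
                  nodesize = nodesize, seed = candidate_seed(strat_seed, tuned$best_mtry))
    pred_cal <- fit$predict(Xc)
    pred_val <- fit$predict(Xv)
    out[[s]] <- list(
      strategy = nm,
      model_kind = "random_forest",
      m_try = tuned$best_mtry,
      n_trees = n_trees,
      nodesize = nodesize,
      oob_rmse = tuned$oob_rmse,
      metrics = evaluate_predictions(cal_som, pred_cal, val_som, pred_val),
      predictions = list(cal = pred_cal, val = pred_val),
      importance = normalize_importance(fit$importance)
    )
  }
  structure(out, class = "strategy_results")
}

#' Summarize strategy results as a table
#'
#' @param results A [run_all_strategies()] result.
#' @return data.frame with one row per strategy: mtry, calibration and
#'   validation R2/RMSE, RPIQ and its category.
#' @export
summarize_strategies <- function(results) {
  stopifnot(inherits(results, "strategy_results"))
  do.call(rbind, lapply(results, function(x) {
    data.frame(strategy = x$strategy, m_try = x$m_try,
               r2_cal = x$metrics$r2_cal, rmse_cal = x$metrics$rmse_cal,
               r2_val = x$metrics$r2_val, rmse_val = x$metrics$rmse_val,
               rpiq = x$metrics$rpiq, category = x$metrics$category,
               row.names = NULL)
  }))
}
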