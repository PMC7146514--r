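#' @keywords internal
#' @aliases somspectra-package
#' @useDynLib somspectra, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Run the full SOM estimation pipeline
#'
#' End-to-end chain on one dataset: preprocessing (trim 400-2400 nm,
#' Gaussian downsample, Savitzky-Golay, continuum removal), rank-ordered 2:1
#' split, PCA features, the exhaustive two-/three-band index search, the six
#' random-forest variable strategies, and (optionally) the rendered report.
#'
#' @param dataset A [soil_dataset] on the raw grid, or \code{NULL} to
#'   generate one from \code{config}.
#' @param config A [synth_config()] used when \code{dataset} is NULL.
#' @param grid_step Downsampling step in nm of the preprocessing chain
#'   (5 nm reproduces the canonical 401-band grid).
#' @param search_step Grid step in nm for the exhaustive index search; the
#'   preprocessed spectra are thinned (see [thin_wavelengths()]) to this
#'   spacing. 5 nm scans the full grid; 10-20 nm give proportionally faster
#'   three-band scans.
#' @param fraction Candidate retention fraction for the index search.
#' @param n_trees Trees per random forest.
#' @param seed Seed for model fitting (data generation uses
#'   \code{config$seed}).
#' @param out_dir If non-NULL, [render_report()] output directory.
#' @param figures Passed to [render_report()].
#' @return List: \code{dataset}, \code{split}, \code{pca} (calibration fit),
#'   \code{score_correlations} (calibration score-SOM r), \code{selected}
#'   (index selection table), \code{results} (strategy fits),
#'   \code{summary} (strategy metric table).
#' @export
run_som_pipeline <- function(dataset = NULL, config = synth_config(),
                             grid_step = 5, search_step = grid_step,
                             fraction = 0.01, n_trees = 1000,
                             seed = 1L, out_dir = NULL, figures = FALSE) {
  if (is.null(dataset)) dataset <- generate_dataset(config)
  prep <- preprocess_spectra(dataset$spectra, step = grid_step)
  ds_sm <- soil_dataset(dataset$som, prep$smoothed, dataset$sample_ids)
  split <- rank_order_split(ds_sm)
  cal <- split$calibration
  val <- split$validation

  cal_cr <- continuum_remove(cal$spectra)
  val_cr <- continuum_remove(val$spectra)

  cal_search <- if (search_step > grid_step) {
    soil_dataset(cal$som, thin_wavelengths(cal$spectra, search_step), cal$sample_ids)
  } else cal
  val_search <- if (search_step > grid_step) {
    soil_dataset(val$som, thin_wavelengths(val$spectra, search_step), val$sample_ids)
  } else val

  search <- search_indices(cal_search, val_search, fraction = fraction)
  features <- build_feature_sets(cal, val, search$selected, cal_cr, val_cr)
  pca <- fit_pca(cal_cr, min_components = 5L)
  results <- run_all_strategies(features, cal$som, val$som,
                                n_trees = n_trees, seed = seed)
  out <- list(
    dataset = dataset,
    split = split,
    pca = pca,
    score_correlations = correlate_scores(
      pca$scores[, seq_len(min(5L, pca$n_retained)), drop = FALSE], cal$som),
    selected = search$selected,
    results = results,
    summary = summarize_strategies(results)
  )
  if (!is.null(out_dir)) {
    render_report(results, cal$som, val$som, selected = search$selected,
                  out_dir = out_dir, figures = figures)
  }
  out
}
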