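#' Render tables and figures for a pipeline run
#'
#' Writes a deterministic file set to \code{out_dir}: a Table-1-style
#' descriptive-statistics CSV, the selected-index table, a strategy summary
#' CSV, full-precision metrics JSON, per-strategy prediction CSVs and 1:1
#' scatter figures with 95% confidence (narrow) and prediction (wide) bands,
#' one normalized-importance bar figure per strategy, and a correlation
#' contour figure per supplied two-band map. Rerunning with identical inputs
#' reproduces identical CSV/JSON content.
#'
#' @param results A [run_all_strategies()] result.
#' @param cal_som,val_som Calibration/validation SOM vectors.
#' @param selected Selection table from [search_indices()] (optional).
#' @param maps Optional named list of two-band [scan_index()] maps to plot.
#' @param out_dir Output directory (created if needed).
#' @param figures Write PNG figures (set FALSE for table-only output).
#' @return Invisibly, the character vector of files written.
#' @export
render_report <- function(results, cal_som, val_som, selected = NULL,
                          maps = NULL, out_dir, figures = TRUE) {
  stopifnot(inherits(results, "strategy_results"), length(results) > 0L)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, name)
    data.table::fwrite(data.table::as.data.table(df), p)
    files <<- c(files, p)
    p
  }

  desc <- rbind(
    cbind(data_set = "entire", describe_values(c(cal_som, val_som))),
    cbind(data_set = "calibration", describe_values(cal_som)),
    cbind(data_set = "validation", describe_values(val_som))
  )
  w(desc, "descriptive_statistics.csv")
  if (!is.null(selected)) w(selected, "selected_indices.csv")
  summary_df <- summarize_strategies(results)
  w(summary_df, "strategy_summary.csv")
  w(data.frame(
    stability_p_r2 = stability_anova(summary_df$r2_cal, summary_df$r2_val),
    stability_p_rmse = stability_anova(summary_df$rmse_cal, summary_df$rmse_val)
  ), "stability_anova.csv")

  mj <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(
    lapply(results, function(x) c(
      list(strategy = x$strategy, m_try = x$m_try),
      unclass(x$metrics),
      list(importance = as.list(x$importance))
    )),
    mj, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, mj)

  for (x in results) {
    tag <- gsub("+", "_", x$strategy, fixed = TRUE)
    w(data.frame(set = rep(c("calibration", "validation"),
                           c(length(cal_som), length(val_som))),
                 observed = c(cal_som, val_som),
                 predicted = c(x$predictions$cal, x$predictions$val)),
      sprintf("predictions_%s.csv", tag))
    w(data.frame(feature = names(x$importance),
                 importance_percent = as.numeric(x$importance)),
      sprintf("importance_%s.csv", tag))
    if (figures) {
      files <- c(files,
                 plot_scatter_11(val_som, x$predictions$val, x$strategy,
                                 file.path(out_dir, sprintf("scatter_%s.png", tag))),
                 plot_importance(x$importance, x$strategy,
                                 file.path(out_dir, sprintf("importance_%s.png", tag))))
    }
  }
  if (figures && !is.null(maps)) {
    for (nm in names(maps)) {
      if (length(dim(maps[[nm]]$r)) == 2L) {
        files <- c(files,
                   plot_correlation_map(maps[[nm]],
                                        file.path(out_dir, sprintf("map_%s.png", nm))))
      }
    }
  }
  invisible(files)
}

plot_scatter_11 <- function(obs, pred, strategy, path) {
  bands <- interval_bands(obs, pred)
  df <- data.frame(obs = obs, pred = pred)
  lim <- range(c(obs, pred, bands$pi_lo, bands$pi_hi))
  p <- ggplot2::ggplot(bands, ggplot2::aes(x = obs)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pi_lo, ymax = pi_hi),
                         fill = "salmon", alpha = 0.5) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = ci_lo, ymax = ci_hi),
                         fill = "#DC143C", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = fit), colour = "red") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "blue",
                         linetype = "dashed") +
    ggplot2::geom_point(data = df, ggplot2::aes(y = pred), size = 1.4) +
    ggplot2::coord_equal(xlim = lim, ylim = lim) +
    ggplot2::labs(x = "Measured SOM (g/kg)", y = "Predicted SOM (g/kg)",
                  title = strategy) +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = 4.5, height = 4.5, dpi = 120)
  path
}

plot_importance <- function(importance, strategy, path) {
  df <- data.frame(feature = factor(names(importance), levels = names(importance)),
                   importance = as.numeric(importance))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = feature, y = importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "Relative importance (%)", title = strategy) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  ggplot2::ggsave(path, p, width = 5, height = 3.5, dpi = 120)
  path
}

plot_correlation_map <- function(map, path) {
  df <- expand.grid(wl_i = map$wavelengths, wl_j = map$wavelengths)
  df$r <- as.vector(map$r)
  p <- ggplot2::ggplot(df, ggplot2::aes(wl_i, wl_j, fill = r)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey90", limits = c(-1, 1)) +
    ggplot2::labs(x = "Wavelength i (nm)", y = "Wavelength j (nm)",
                  title = paste0(map$form, " correlation with SOM")) +
    ggplot2::theme_bw()
  ggplot2::ggsave(path, p, width = 5, height = 4.2, dpi = 120)
  path
}
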