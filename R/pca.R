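#' Principal component analysis of spectra
#'
#' PCA of the column-centered reflectance matrix (centering only; all
#' wavelengths share units, so no variance scaling). Components are ordered
#' by decreasing explained variance. The number retained is the smallest k
#' whose cumulative explained-variance ratio exceeds \code{cum_threshold},
#' with a floor of \code{min_components} (default 5, the number of scores
#' carried into modeling) when that many exist. Each loading vector is
#' oriented so its largest-magnitude element is positive, making repeated
#' fits bit-stable.
#'
#' @param spectra A [spectra_set] with at least 2 samples, typically
#'   continuum-removed spectra.
#' @param cum_threshold Cumulative explained-variance ratio to exceed.
#' @param min_components Floor on the number of retained components.
#' @return Object of class \code{pca_result}: \code{loadings}
#'   (k x n_wavelengths, rows unit-norm orthogonal), \code{explained_ratio}
#'   (all components, non-increasing), \code{scores} (n_samples x k),
#'   \code{center} (mean spectrum), \code{n_retained}, \code{wavelengths}.
#' @export
fit_pca <- function(spectra, cum_threshold = 0.95, min_components = 5L) {
  stopifnot(inherits(spectra, "spectra_set"))
  x <- spectra$reflectance
  if (nrow(x) < 2L) stop("need at least 2 samples")
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  if (sum(xc^2) < 1e-24) stop("constant matrix: no variance to decompose")
  sv <- svd(xc)
  ev <- sv$d^2
  ratio <- ev / sum(ev)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  k95 <- which(cumsum(ratio) > cum_threshold)[1]
  if (is.na(k95)) k95 <- ncomp
  k <- min(max(k95, min_components), ncomp)
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])
  # sign convention: largest-magnitude element of each loading positive
  for (i in seq_len(k)) {
    j <- which.max(abs(loadings[i, ]))
    if (loadings[i, j] < 0) loadings[i, ] <- -loadings[i, ]
  }
  scores <- xc %*% t(loadings)
  colnames(scores) <- rownames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(loadings = loadings, explained_ratio = ratio, scores = scores,
         center = center, n_retained = k, wavelengths = spectra$wavelengths,
         sample_ids = spectra$sample_ids),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d components retained (cumulative ratio %.3f)\n",
              x$n_retained, sum(x$explained_ratio[seq_len(x$n_retained)])))
  invisible(x)
}

#' Project spectra onto a fitted PCA basis
#'
#' Computes \code{(X - center) \%*\% t(loadings)}. Used to obtain validation
#' scores from a calibration-only fit, avoiding information leakage.
#'
#' @param result A [fit_pca()] result.
#' @param spectra A [spectra_set] on the same wavelength grid as the fit.
#' @return Score matrix (n_samples x n_retained).
#' @export
project_pca <- function(result, spectra) {
  stopifnot(inherits(result, "pca_result"), inherits(spectra, "spectra_set"))
  if (length(spectra$wavelengths) != length(result$wavelengths) ||
      any(abs(spectra$wavelengths - result$wavelengths) > 1e-9)) {
    stop("wavelength grid mismatch with the PCA fit")
  }
  sweep(spectra$reflectance, 2L, result$center) %*% t(result$loadings)
}

#' Pearson correlations between PCA scores and SOM
#'
#' @param scores Score matrix (samples x components).
#' @param som Numeric vector, same length as rows of \code{scores}.
#' @return Named numeric vector of Pearson r, one per component; \code{NA}
#'   for zero-variance score columns.
#' @export
correlate_scores <- function(scores, som) {
  scores <- as.matrix(scores)
  som <- as.numeric(som)
  if (nrow(scores) != length(som)) stop("length mismatch")
  if (length(som) < 3L) stop("need at least 3 samples")
  r <- apply(scores, 2L, function(v) {
    if (stats::sd(v) < 1e-12) return(NA_real_)
    stats::cor(v, som)
  })
  if (is.null(names(r))) names(r) <- paste0("PC", seq_along(r))
  r
}
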