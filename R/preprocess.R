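#' Trim a spectra set to a wavelength window
#'
#' Keeps wavelengths \code{w} with \code{lo <= w <= hi} (closed interval);
#' sample order is unchanged. On a 350-2500 nm, 1-nm grid, trimming to
#' [400, 2400] keeps 2001 bands (the low signal-to-noise spectrometer fringe
#' is discarded).
#'
#' @param spectra A [spectra_set].
#' @param lo,hi Window bounds in nm, \code{lo < hi}.
#' @return A [spectra_set] on the trimmed grid.
#' @export
trim_wavelengths <- function(spectra, lo = 400, hi = 2400) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (lo >= hi) stop("lo must be < hi")
  keep <- spectra$wavelengths >= lo & spectra$wavelengths <= hi
  if (!any(keep)) stop("trim window contains no wavelengths")
  spectra_set(spectra$wavelengths[keep],
              spectra$reflectance[, keep, drop = FALSE],
              spectra$sample_ids)
}

#' Gaussian-filter downsampling of spectra
#'
#' Resamples a uniform wavelength grid to nodes \code{lo, lo+step, ..., hi}.
#' Each output value is a Gaussian-kernel weighted average of the input
#' spectrum, kernel centered at the output node, truncated at +/- 3 sigma and
#' renormalized at the grid edges. Combines smoothing and resampling in one
#' pass; output values are convex combinations of inputs, hence bounded by
#' the per-spectrum input min/max. 2001 bands at 1 nm over 400-2400 nm with
#' \code{step = 5} yield 401 bands.
#'
#' @param spectra A [spectra_set] on a uniform grid.
#' @param step Output spacing in nm (> 0).
#' @param sigma Kernel standard deviation in nm; default \code{step/2.355}
#'   (FWHM equal to the output spacing).
#' @return A [spectra_set] on the coarser grid.
#' @export
gaussian_downsample <- function(spectra, step = 5, sigma = step / 2.355) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (step <= 0) stop("step must be > 0")
  if (sigma <= 0) stop("sigma must be > 0")
  wl <- spectra$wavelengths
  d <- diff(wl)
  if (max(d) - min(d) > 1e-8) stop("input grid must be uniform")
  span <- max(wl) - min(wl)
  if (step > span) stop("step larger than the grid span")
  out_wl <- seq(min(wl), max(wl), by = step)
  # weight matrix: n_out x n_in, truncated at 3 sigma, rows renormalized
  w <- outer(out_wl, wl, function(a, b) {
    z <- (b - a) / sigma
    ifelse(abs(z) <= 3, exp(-z^2 / 2), 0)
  })
  w <- w / rowSums(w)
  out <- spectra$reflectance %*% t(w)
  spectra_set(out_wl, out, spectra$sample_ids)
}

#' Savitzky-Golay smoothing
#'
#' Applies a Savitzky-Golay filter (local least-squares polynomial) along the
#' wavelength axis of every spectrum, the standard noise-reduction step for
#' Vis-NIR soil spectra. Defaults: polynomial order 2, window 11 bands.
#' Edges use the filter's one-sided polynomial fits, so the grid length is
#' preserved with no NA bands; any spectrum that is exactly a polynomial of
#' degree <= \code{polyorder} passes through unchanged.
#'
#' @param spectra A [spectra_set].
#' @param window Odd window length in bands, \code{> polyorder} and no longer
#'   than the grid.
#' @param polyorder Polynomial order.
#' @return A smoothed [spectra_set] on the same grid.
#' @export
savgol_smooth <- function(spectra, window = 11, polyorder = 2) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (window %% 2 != 1) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > length(spectra$wavelengths)) stop("window longer than the grid")
  out <- t(apply(spectra$reflectance, 1L, signal::sgolayfilt,
                 p = polyorder, n = window))
  spectra_set(spectra$wavelengths, out, spectra$sample_ids)
}

# Upper convex hull (Andrew's monotone chain) of (x, y); x strictly
# increasing. Returns indices of hull vertices, first and last always kept;
# collinear points are retained (ties on the hull keep both points).
upper_hull_idx <- function(x, y) {
  n <- length(x)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    while (top >= 2L) {
      a <- stack[top - 1L]; b <- stack[top]
      # pop b if it lies strictly below segment a-i
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross > 0) top <- top - 1L else break
    }
    top <- top + 1L
    stack[top] <- i
  }
  stack[seq_len(top)]
}

#' Continuum removal
#'
#' Divides each spectrum by its upper convex hull (the continuum), isolating
#' absorption features: \code{CR(w) = R(w) / H(w)}. Output lies in (0, 1];
#' the first and last band and every hull-touching band are exactly 1. The
#' transform is idempotent.
#'
#' @param spectra A [spectra_set] with strictly positive reflectance.
#' @return A [spectra_set] of continuum-removed spectra.
#' @export
continuum_remove <- function(spectra) {
  stopifnot(inherits(spectra, "spectra_set"))
  wl <- spectra$wavelengths
  if (length(wl) < 2L) stop("continuum removal needs at least 2 bands")
  if (any(spectra$reflectance <= 0)) stop("reflectance must be > 0")
  out <- spectra$reflectance
  for (i in seq_len(nrow(out))) {
    y <- out[i, ]
    h_idx <- upper_hull_idx(wl, y)
    hull <- stats::approx(wl[h_idx], y[h_idx], xout = wl)$y
    cr <- pmin(y / hull, 1)
    cr[h_idx] <- 1
    out[i, ] <- cr
  }
  spectra_set(wl, out, spectra$sample_ids)
}

#' Thin a spectra set to a coarser wavelength grid
#'
#' Keeps every band whose offset from the first wavelength is a multiple of
#' \code{step}. Used to run the exhaustive band search on a coarser grid
#' (e.g. every 10 or 20 nm) after the canonical preprocessing; unlike
#' re-running [gaussian_downsample()] or [savgol_smooth()] at a coarser
#' grid, thinning does not change the spectral resolution of the retained
#' bands.
#'
#' @param spectra A [spectra_set].
#' @param step Grid step in nm; must be a multiple of the current spacing.
#' @return A [spectra_set] on the thinned grid.
#' @export
thin_wavelengths <- function(spectra, step) {
  stopifnot(inherits(spectra, "spectra_set"))
  wl <- spectra$wavelengths
  keep <- abs((wl - wl[1]) %% step) < 1e-9
  if (sum(keep) < 2L) stop("thinning step too coarse for the grid")
  spectra_set(wl[keep], spectra$reflectance[, keep, drop = FALSE],
              spectra$sample_ids)
}

#' Standard preprocessing chain
#'
#' trim (400-2400 nm) -> Gaussian downsample (5 nm) -> Savitzky-Golay
#' (order 2, window 11), plus the continuum-removed version of the smoothed
#' output. Each stage preserves sample count and order.
#'
#' @param spectra A [spectra_set] (raw grid, e.g. 350-2500 nm at 1 nm).
#' @param trim_lo,trim_hi Trim window (nm).
#' @param step Downsampling step (nm).
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @return List with elements \code{smoothed} and \code{cr}, both
#'   [spectra_set]s on the downsampled grid.
#' @export
preprocess_spectra <- function(spectra, trim_lo = 400, trim_hi = 2400,
                               step = 5, sg_window = 11, sg_order = 2) {
  sm <- savgol_smooth(
    gaussian_downsample(trim_wavelengths(spectra, trim_lo, trim_hi), step = step),
    window = sg_window, polyorder = sg_order
  )
  list(smoothed = sm, cr = continuum_remove(sm))
}
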