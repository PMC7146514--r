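#' Spectral index forms
#'
#' The ten algebraic index forms scanned against SOM. Two-band forms
#' (\code{Ri}, \code{Rj} reflectance at two distinct wavelengths):
#' \itemize{
#'   \item SI, sum index: \code{Ri + Rj}
#'   \item DI, difference index: \code{Ri - Rj}
#'   \item PI, product index: \code{Ri * Rj}
#'   \item RI, ratio index: \code{Ri / Rj}
#'   \item NDI, normalized difference index: \code{(Ri - Rj) / (Ri + Rj)}
#' }
#' Three-band forms (\code{Rk} a third distinct wavelength):
#' \itemize{
#'   \item TBI1: \code{Ri / (Rj + Rk)}
#'   \item TBI2: \code{(Ri + Rj) / Rk}
#'   \item TBI3: \code{(Ri - Rj) / (Rj - Rk)}
#'   \item TBI4: \code{(Ri - Rj) / (Ri + Rj - 2 Rk)}
#'   \item TBI5: \code{Ri + Rj - 2 Rk}
#' }
#' @format Character vectors of form names.
#' @name index_forms
NULL

#' @rdname index_forms
#' @export
TWO_BAND_FORMS <- c("SI", "DI", "PI", "RI", "NDI")

#' @rdname index_forms
#' @export
THREE_BAND_FORMS <- c("TBI1", "TBI2", "TBI3", "TBI4", "TBI5")

form_code <- function(form) {
  match(form, c(TWO_BAND_FORMS, THREE_BAND_FORMS))
}

#' Arity of an index form
#' @param form Form name (see [index_forms]).
#' @return 2 or 3.
#' @export
form_arity <- function(form) {
  code <- form_code(form)
  if (is.na(code)) stop("unknown index form: ", form)
  if (code <= 5L) 2L else 3L
}

# Vectorized form evaluation on reflectance columns (matrices or vectors of
# equal shape). Division by a near-zero denominator yields NaN -> flagged by
# callers, never silently propagated into correlations.
eval_form <- function(form, ri, rj, rk = NULL, eps = 1e-12) {
  guard <- function(den) ifelse(abs(den) < eps, NaN, den)
  switch(form,
    SI = ri + rj,
    DI = ri - rj,
    PI = ri * rj,
    RI = ri / guard(rj),
    NDI = (ri - rj) / guard(ri + rj),
    TBI1 = ri / guard(rj + rk),
    TBI2 = (ri + rj) / guard(rk),
    TBI3 = (ri - rj) / guard(rj - rk),
    TBI4 = (ri - rj) / guard(ri + rj - 2 * rk),
    TBI5 = ri + rj - 2 * rk,
    stop("unknown index form: ", form)
  )
}

#' Evaluate a spectral index at given wavelengths
#'
#' Applies an index form per sample at the requested (distinct, on-grid)
#' wavelengths. Samples where the form is undefined (denominator magnitude
#' below \code{eps}) are returned as \code{NaN} and should be treated as
#' flagged, not as values.
#'
#' @param form Form name (see [index_forms]).
#' @param spectra A [spectra_set].
#' @param bands Numeric vector of 2 or 3 wavelengths (nm), matching the
#'   form's arity, all distinct and on the grid.
#' @param eps Degeneracy threshold for denominators.
#' @return Numeric vector, one value per sample (NaN where undefined).
#' @export
index_values <- function(form, spectra, bands, eps = 1e-12) {
  stopifnot(inherits(spectra, "spectra_set"))
  arity <- form_arity(form)
  if (length(bands) != arity) {
    stop(sprintf("form %s needs %d wavelengths", form, arity))
  }
  if (anyDuplicated(bands)) stop("wavelengths must be distinct")
  idx <- match(bands, spectra$wavelengths)
  if (anyNA(idx)) stop("wavelength not on the spectra grid: ",
                       paste(bands[is.na(idx)], collapse = ", "))
  rr <- spectra$reflectance
  eval_form(form, rr[, idx[1]], rr[, idx[2]],
            if (arity == 3L) rr[, idx[3]], eps = eps)
}
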