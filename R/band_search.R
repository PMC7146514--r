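#' Exhaustive correlation scan of an index form
#'
#' Computes the Pearson correlation between SOM and the index value at every
#' ordered combination of distinct wavelengths (all \eqn{B^2} or \eqn{B^3}
#' cells of the preprocessed grid). Cells where the index is non-finite for
#' any sample, where any denominator magnitude falls below \code{eps}, or
#' where the index variance is below \code{eps} are marked invalid; repeated
#' wavelengths are always invalid. Three-band scans can be chunked along the
#' first wavelength axis to cap working memory; chunked and unchunked scans
#' are bit-identical.
#'
#' @param form Index form name (see [index_forms]).
#' @param spectra Calibration [spectra_set].
#' @param som Calibration SOM vector (>= 3 samples, non-constant).
#' @param eps Degeneracy threshold.
#' @param chunk_size Number of first-axis wavelengths per chunk for
#'   three-band scans; \code{NULL} scans in one pass.
#' @return Object of class \code{correlation_map}: \code{form},
#'   \code{wavelengths}, \code{r} (B x B matrix or B x B x B array, NA where
#'   invalid) and \code{valid} (logical, same shape).
#' @export
scan_index <- function(form, spectra, som, eps = 1e-12, chunk_size = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  som <- as.numeric(som)
  if (length(som) != nrow(spectra$reflectance)) stop("som length mismatch")
  if (length(som) < 3L) stop("need at least 3 calibration samples")
  if (stats::sd(som) < eps) stop("SOM variance is zero")
  code <- form_code(form)
  if (is.na(code)) stop("unknown index form: ", form)
  B <- length(spectra$wavelengths)
  rr <- spectra$reflectance
  if (code <= 5L) {
    res <- scan_pairs_cpp(rr, som, code, eps)
    r <- res$r
    valid <- res$valid
  } else {
    if (is.null(chunk_size)) chunk_size <- B
    r <- array(NA_real_, dim = c(B, B, B))
    valid <- array(FALSE, dim = c(B, B, B))
    starts <- seq(0L, B - 1L, by = chunk_size)
    for (i0 in starts) {
      i1 <- min(i0 + chunk_size, B)
      slab <- scan_triples_cpp(rr, som, code, eps, i0, i1)
      dim(slab$r) <- c(i1 - i0, B, B)
      dim(slab$valid) <- c(i1 - i0, B, B)
      r[(i0 + 1L):i1, , ] <- slab$r
      valid[(i0 + 1L):i1, , ] <- slab$valid
    }
  }
  structure(
    list(form = form, wavelengths = spectra$wavelengths, r = r, valid = valid),
    class = "correlation_map"
  )
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("CorrelationMap %s: %d^%d cells, %d valid, max |r| = %.3f\n",
              x$form, length(x$wavelengths), length(dim(x$r)),
              sum(x$valid), max(abs(x$r[x$valid]))))
  invisible(x)
}

#' Retain the top fraction of band combinations by |r|
#'
#' Ranks valid cells by decreasing |r| and keeps the
#' \code{ceiling(fraction * n_valid)} best, the scan's candidate-retention
#' step (default: top 1%). Ties are broken deterministically by signed r,
#' then by ascending wavelength indices.
#'
#' @param map A [scan_index()] result.
#' @param fraction Fraction of valid cells to keep, in (0, 1].
#' @return A data.frame (class \code{index_candidates}) with the form, one
#'   \code{wl_*} column per axis, and \code{r_cal}, ordered by decreasing
#'   |r_cal|.
#' @export
top_candidates <- function(map, fraction = 0.01) {
  stopifnot(inherits(map, "correlation_map"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  vidx <- which(map$valid)
  if (length(vidx) == 0L) stop("no valid cells in the map")
  n_keep <- ceiling(fraction * length(vidx))
  rv <- map$r[vidx]
  ord <- order(-abs(rv), -rv, vidx)
  keep <- vidx[ord[seq_len(n_keep)]]
  dims <- dim(map$r)
  sub <- arrayInd(keep, dims)
  out <- data.frame(form = rep(map$form, n_keep), stringsAsFactors = FALSE)
  axis_names <- c("wl_i", "wl_j", "wl_k")[seq_along(dims)]
  for (a in seq_along(dims)) out[[axis_names[a]]] <- map$wavelengths[sub[, a]]
  out$r_cal <- map$r[keep]
  class(out) <- c("index_candidates", "data.frame")
  out
}

#' Select the optimal band combination
#'
#' For every retained candidate, recomputes the index on the validation set
#' and its Pearson correlation \code{r_val} with validation SOM; returns the
#' candidate minimizing \code{err = |r_cal - r_val|} (the
#' calibration/validation correlation error). Candidates undefined or
#' degenerate on the validation samples are dropped. Ties are broken by
#' larger |r_cal|, then by lexicographically smallest wavelengths.
#'
#' @param candidates A [top_candidates()] data.frame.
#' @param val_spectra Validation [spectra_set].
#' @param val_som Validation SOM vector (>= 3 samples).
#' @param eps Degeneracy threshold.
#' @return One-row data.frame (class \code{selected_index}): form,
#'   wavelengths, \code{r_cal}, \code{r_val}, \code{err}.
#' @export
select_optimal <- function(candidates, val_spectra, val_som, eps = 1e-12) {
  stopifnot(inherits(candidates, "data.frame"), nrow(candidates) > 0L)
  stopifnot(inherits(val_spectra, "spectra_set"))
  val_som <- as.numeric(val_som)
  if (length(val_som) < 3L) stop("need at least 3 validation samples")
  form <- as.character(candidates$form[1])
  arity <- form_arity(form)
  idx_i <- match(candidates$wl_i, val_spectra$wavelengths)
  idx_j <- match(candidates$wl_j, val_spectra$wavelengths)
  if (anyNA(idx_i) || anyNA(idx_j)) stop("candidate wavelength off the validation grid")
  rr <- val_spectra$reflectance
  if (arity == 3L) {
    idx_k <- match(candidates$wl_k, val_spectra$wavelengths)
    if (anyNA(idx_k)) stop("candidate wavelength off the validation grid")
    v <- eval_form(form, rr[, idx_i, drop = FALSE], rr[, idx_j, drop = FALSE],
                   rr[, idx_k, drop = FALSE], eps = eps)
  } else {
    v <- eval_form(form, rr[, idx_i, drop = FALSE], rr[, idx_j, drop = FALSE],
                   eps = eps)
  }
  v <- matrix(v, nrow = nrow(rr))
  ok <- apply(v, 2L, function(col) all(is.finite(col)) && stats::sd(col) >= eps)
  if (!any(ok)) stop("all candidates undefined on the validation set")
  r_val <- rep(NA_real_, ncol(v))
  r_val[ok] <- suppressWarnings(as.numeric(stats::cor(v[, ok, drop = FALSE], val_som)))
  err <- abs(candidates$r_cal - r_val)
  pool <- which(ok)
  key <- cbind(err[pool], -abs(candidates$r_cal[pool]),
               candidates$wl_i[pool], candidates$wl_j[pool],
               if (arity == 3L) candidates$wl_k[pool] else 0)
  best <- pool[do.call(order, as.data.frame(key))[1]]
  out <- candidates[best, , drop = FALSE]
  out$r_val <- r_val[best]
  out$err <- err[best]
  rownames(out) <- NULL
  class(out) <- c("selected_index", "data.frame")
  out
}

#' Slice views of a correlation map
#'
#' For a three-band map, extracts the 2-D slices through the optimal
#' combination orthogonal to each axis (the "optimal slice maps"); for a
#' two-band map, returns the full matrix (contour view). Raw arrays are
#' returned for plotting or testing.
#'
#' @param map A [scan_index()] result.
#' @param best A [select_optimal()] row on the same grid.
#' @return For arity 3: list with \code{slice_i}, \code{slice_j},
#'   \code{slice_k} (each B x B, the plane through the optimal wavelength on
#'   that axis) and \code{best}. For arity 2: list with \code{map_r} and
#'   \code{best}.
#' @export
slice_views <- function(map, best) {
  stopifnot(inherits(map, "correlation_map"))
  dims <- dim(map$r)
  pos_i <- match(best$wl_i, map$wavelengths)
  pos_j <- match(best$wl_j, map$wavelengths)
  if (is.na(pos_i) || is.na(pos_j)) stop("best combination not on the map grid")
  if (length(dims) == 2L) {
    return(list(map_r = map$r, best = best))
  }
  pos_k <- match(best$wl_k, map$wavelengths)
  if (is.na(pos_k)) stop("best combination not on the map grid")
  list(
    slice_i = map$r[pos_i, , ],
    slice_j = map$r[, pos_j, ],
    slice_k = map$r[, , pos_k],
    best = best
  )
}

#' Run the full optimal band-combination search
#'
#' Scans each requested form on the calibration set, keeps the top
#' \code{fraction} of combinations and selects the optimal one by minimum
#' calibration/validation correlation error.
#'
#' @param cal,val Calibration and validation [soil_dataset]s whose spectra
#'   are already preprocessed to the search grid.
#' @param forms Character vector of form names.
#' @param fraction Candidate retention fraction.
#' @param eps Degeneracy threshold.
#' @param chunk_size Passed to [scan_index()].
#' @param keep_maps Keep the full correlation maps in the result (memory!).
#' @return List with \code{selected} (data.frame, one row per form,
#'   including \code{r_max}, the strongest calibration correlation the form
#'   achieved anywhere on the grid) and, if requested, \code{maps} (named
#'   list of correlation maps).
#' @export
search_indices <- function(cal, val, forms = c(TWO_BAND_FORMS, THREE_BAND_FORMS),
                           fraction = 0.01, eps = 1e-12, chunk_size = NULL,
                           keep_maps = FALSE) {
  stopifnot(inherits(cal, "soil_dataset"), inherits(val, "soil_dataset"))
  selected <- vector("list", length(forms))
  maps <- if (keep_maps) stats::setNames(vector("list", length(forms)), forms)
  for (idx in seq_along(forms)) {
    fm <- forms[idx]
    map <- scan_index(fm, cal$spectra, cal$som, eps = eps, chunk_size = chunk_size)
    cand <- top_candidates(map, fraction = fraction)
    sel <- select_optimal(cand, val$spectra, val$som, eps = eps)
    if (form_arity(fm) == 2L && !("wl_k" %in% names(sel))) sel$wl_k <- NA_real_
    sel$r_max <- cand$r_cal[1]  # strongest calibration correlation of the form
    selected[[idx]] <- sel
    if (keep_maps) maps[[fm]] <- map
  }
  selected <- do.call(rbind, lapply(selected, function(d) {
    d[, c("form", "wl_i", "wl_j", "wl_k", "r_cal", "r_val", "err", "r_max")]
  }))
  out <- list(selected = selected)
  if (keep_maps) out$maps <- maps
  out
}
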