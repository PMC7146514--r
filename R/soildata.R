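#' Construct a SpectraSet
#'
#' A \code{SpectraSet} couples a strictly increasing wavelength grid (nm)
#' with a samples-by-wavelengths reflectance matrix in (0, 1].
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance Numeric matrix, one row per sample, one column per
#'   wavelength. All values finite and in (0, 1].
#' @param sample_ids Character vector of unique sample identifiers. Defaults
#'   to \code{"s0001"} style labels.
#' @return An object of class \code{spectra_set} with elements
#'   \code{wavelengths}, \code{reflectance}, \code{sample_ids}.
#' @export
spectra_set <- function(wavelengths, reflectance, sample_ids = NULL) {
  wavelengths <- as.numeric(wavelengths)
  if (is.null(dim(reflectance))) {
    reflectance <- matrix(reflectance, nrow = 1L)
  }
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (length(wavelengths) != ncol(reflectance)) {
    stop("number of wavelengths must equal number of reflectance columns")
  }
  if (length(wavelengths) < 1L) stop("empty wavelength grid")
  if (any(diff(wavelengths) <= 0)) stop("wavelengths must be strictly increasing")
  if (any(!is.finite(reflectance))) stop("reflectance must be finite (no NaN/Inf)")
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(nrow(reflectance)))
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(reflectance)) {
    stop("sample_ids length must equal number of spectra rows")
  }
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  dimnames(reflectance) <- NULL
  structure(
    list(wavelengths = wavelengths, reflectance = reflectance,
         sample_ids = sample_ids),
    class = "spectra_set"
  )
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("SpectraSet: %d samples x %d bands (%.0f-%.0f nm)\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$reflectance)

#' Construct a SoilDataset
#'
#' Pairs per-sample SOM measurements (g/kg) with their spectra.
#'
#' @param som Numeric vector of SOM contents in g/kg, strictly positive.
#' @param spectra A [spectra_set] with one row per SOM value.
#' @param sample_ids Optional identifiers; defaults to the spectra ids.
#' @return Object of class \code{soil_dataset} with elements \code{sample_ids},
#'   \code{som} and \code{spectra}.
#' @export
soil_dataset <- function(som, spectra, sample_ids = NULL) {
  stopifnot(inherits(spectra, "spectra_set"))
  som <- as.numeric(som)
  if (length(som) == 0L) stop("empty dataset")
  if (any(!is.finite(som)) || any(som <= 0)) {
    stop("som must be finite and strictly positive")
  }
  if (length(som) != nrow(spectra$reflectance)) {
    stop("length of som must equal number of spectra rows")
  }
  if (is.null(sample_ids)) sample_ids <- spectra$sample_ids
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (length(sample_ids) != length(som)) stop("sample_ids length mismatch")
  spectra$sample_ids <- sample_ids
  structure(list(sample_ids = sample_ids, som = som, spectra = spectra),
            class = "soil_dataset")
}

#' @export
print.soil_dataset <- function(x, ...) {
  cat(sprintf("SoilDataset: %d samples, SOM %.2f-%.2f g/kg\n",
              length(x$som), min(x$som), max(x$som)))
  print(x$spectra)
  invisible(x)
}

#' Subset a soil dataset by sample index
#'
#' @param dataset A [soil_dataset].
#' @param idx Integer or logical index over samples.
#' @return A [soil_dataset] with the selected samples, order as in \code{idx}.
#' @export
subset_samples <- function(dataset, idx) {
  stopifnot(inherits(dataset, "soil_dataset"))
  sp <- dataset$spectra
  soil_dataset(
    som = dataset$som[idx],
    spectra = spectra_set(sp$wavelengths,
                          sp$reflectance[idx, , drop = FALSE],
                          sp$sample_ids[idx])
  )
}

wavelength_colnames <- function(wavelengths) {
  sprintf("R%04d", as.integer(round(wavelengths)))
}

#' Write a soil dataset to wide CSV
#'
#' Columns: \code{sample_id}, \code{som_g_kg}, then one reflectance column per
#' wavelength named \code{R0350}, \code{R0351}, ... Values are written at full
#' double precision so a read-back round-trips to better than 1e-9 relative
#' error.
#'
#' @param dataset A [soil_dataset].
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "soil_dataset"))
  sp <- dataset$spectra
  df <- data.table::data.table(
    sample_id = dataset$sample_ids,
    som_g_kg = dataset$som
  )
  refl <- data.table::as.data.table(sp$reflectance)
  data.table::setnames(refl, wavelength_colnames(sp$wavelengths))
  df <- cbind(df, refl)
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read a soil dataset from wide CSV
#'
#' Inverse of [write_dataset()]; the wavelength grid is parsed from the
#' \code{R<nnnn>} column names.
#'
#' @param path CSV path written by [write_dataset()].
#' @return A [soil_dataset].
#' @export
read_dataset <- function(path) {
  df <- data.table::fread(path)
  wl_cols <- grep("^R[0-9]{4}$", names(df), value = TRUE)
  if (length(wl_cols) == 0L) stop("no reflectance columns found")
  wl <- as.numeric(sub("^R", "", wl_cols))
  refl <- as.matrix(df[, wl_cols, with = FALSE])
  soil_dataset(
    som = df$som_g_kg,
    spectra = spectra_set(wl, refl, df$sample_id)
  )
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
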