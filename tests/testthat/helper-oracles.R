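# Independent oracles and small fixture builders, written against base R
# only (no package internals), so they stay independent of the code paths
# they check.

# Naive per-cell Pearson scan: loops every ordered tuple of distinct bands,
# evaluates the index formula directly, and calls stats::cor. Mirrors the
# validity rules: any non-finite value, any |denominator| < eps, or index
# variance < eps invalidates a cell.
naive_scan <- function(form, refl, som, eps = 1e-12) {
  B <- ncol(refl)
  formulas2 <- list(
    SI = function(a, b) a + b,
    DI = function(a, b) a - b,
    PI = function(a, b) a * b,
    RI = function(a, b) if (any(abs(b) < eps)) NULL else a / b,
    NDI = function(a, b) if (any(abs(a + b) < eps)) NULL else (a - b) / (a + b)
  )
  formulas3 <- list(
    TBI1 = function(a, b, c) if (any(abs(b + c) < eps)) NULL else a / (b + c),
    TBI2 = function(a, b, c) if (any(abs(c) < eps)) NULL else (a + b) / c,
    TBI3 = function(a, b, c) if (any(abs(b - c) < eps)) NULL else (a - b) / (b - c),
    TBI4 = function(a, b, c) {
      d <- a + b - 2 * c
      if (any(abs(d) < eps)) NULL else (a - b) / d
    },
    TBI5 = function(a, b, c) a + b - 2 * c
  )
  cell_r <- function(v) {
    if (is.null(v) || any(!is.finite(v))) return(NA_real_)
    m <- mean(v)
    if (mean((v - m)^2) < eps) return(NA_real_)
    stats::cor(v, som)
  }
  if (form %in% names(formulas2)) {
    f <- formulas2[[form]]
    r <- matrix(NA_real_, B, B)
    for (i in seq_len(B)) for (j in seq_len(B)) {
      if (i == j) next
      r[i, j] <- cell_r(f(refl[, i], refl[, j]))
    }
  } else {
    f <- formulas3[[form]]
    r <- array(NA_real_, c(B, B, B))
    for (i in seq_len(B)) for (j in seq_len(B)) for (k in seq_len(B)) {
      if (i == j || j == k || i == k) next
      r[i, j, k] <- cell_r(f(refl[, i], refl[, j], refl[, k]))
    }
  }
  r
}

# Small random positive spectra matrix + correlated target for scan tests.
toy_scan_data <- function(n = 30, B = 10, seed = 7) {
  set.seed(seed)
  som <- exp(rnorm(n, 1.5, 0.8))
  refl <- matrix(runif(n * B, 0.2, 0.8), n, B)
  refl[, 3] <- refl[, 3] * exp(-0.01 * som)  # one SOM-sensitive band
  list(refl = refl, som = som,
       spectra = spectra_set(seq(500, by = 10, length.out = B), refl))
}

# Flat spectrum with one Gaussian trough, for continuum-removal checks.
flat_trough_spectra <- function(depth = 0.2, center = 1500, sigma = 40) {
  wl <- seq(1000, 2000, by = 10)
  r <- 1 - depth * exp(-(wl - center)^2 / (2 * sigma^2))
  spectra_set(wl, matrix(r, 1))
}

# Small default-config variant: full wavelength range, fewer samples where a
# test does not need all 168.
quick_config <- function(...) synth_config(...)
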