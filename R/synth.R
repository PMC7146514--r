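#' Synthetic soil-spectra generator configuration
#'
#' Defines the study conditions the generator emulates: a right-skewed SOM
#' distribution (lognormal, truncated), a 350-2500 nm reflectance grid at
#' 1 nm, SOM-driven darkening strongest over 400-700 nm, water/clay
#' absorption troughs near 1400/1900/2200 nm, a SOM-linked narrow clay-band
#' trough whose depth grows linearly with SOM, and structured per-sample
#' variation (albedo, continuum slope, moisture) on top of instrument noise.
#'
#' @param n_samples Number of soil samples (>= 2).
#' @param som_mean,som_sd Target mean and standard deviation of the
#'   underlying lognormal SOM distribution, g/kg.
#' @param som_min,som_max Truncation bounds for SOM, g/kg.
#' @param wavelength_start,wavelength_end,wavelength_step Grid in nm.
#' @param darkening_strength Exponential darkening rate per g/kg SOM applied
#'   through a visible-band weight profile (maximal over 400-700 nm).
#' @param absorption_centers Centers (nm) of the fixed absorption troughs.
#' @param absorption_depths Fractional trough depths in [0, 1), one per center.
#' @param absorption_sigmas Gaussian trough widths (nm), one per center.
#' @param som_linked_feature_center Center (nm) of the trough whose depth is
#'   linear in SOM; must be one of \code{absorption_centers}.
#' @param som_feature_depth_slope Added trough depth per g/kg SOM at the
#'   SOM-linked center.
#' @param vis_chromophore_center,vis_chromophore_sigma,vis_chromophore_depth
#'   Broad visible absorption (iron oxides and similar chromophores) scaled
#'   by an independent per-sample latent; decouples visible brightness from
#'   SOM so the visible darkening trend is real but noisy, as in field soils.
#' @param clay_feature_center,clay_feature_sigma,clay_feature_depth A
#'   concentric broad absorption overlapping the SOM-linked feature, scaled
#'   by an independent per-sample clay latent (uniform on [0, 1]).
#' @param aliphatic_feature_center,aliphatic_feature_sigma,aliphatic_feature_depth
#'   Independent aliphatic C-H absorption near 1730 nm (own latent).
#' @param carbonate_feature_center,carbonate_feature_sigma,carbonate_feature_depth
#'   Independent carbonate absorption near 2340 nm (own latent). Together
#'   with the water, clay and illite bands these fill the leading principal
#'   components, as mineral variation does in real soil libraries.
#' @param illite_feature_center,illite_feature_sigma,illite_feature_depth A
#'   second, offset narrow absorption overlapping the SOM-linked region,
#'   scaled by its own independent latent. With two independent confounders
#'   overlapping the SOM band, a two-band index can null only one of them
#'   while a three-band index can null both; this is what gives three-band
#'   indices their systematic edge, mirroring real clay-mineral
#'   interference around 2200 nm.
#' @param moisture_depth_range Multiplicative range for moisture scaling of
#'   the non-SOM troughs (a per-sample uniform moisture latent maps to this
#'   interval).
#' @param moisture_slope Maximal fractional long-wavelength continuum
#'   depression per unit moisture beyond 1900 nm.
#' @param baseline_tilt_sd Standard deviation of the per-sample log-linear
#'   continuum slope (particle-size/scatter variation).
#' @param albedo_sd Standard deviation of the per-sample log-albedo factor.
#' @param noise_sd_multiplicative,noise_sd_additive Gaussian noise scales.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return Object of class \code{synth_config} (a validated list).
#' @export
synth_config <- function(n_samples = 168,
                         som_mean = 7.46, som_sd = 8.75,
                         som_min = 0.26, som_max = 45.71,
                         wavelength_start = 350, wavelength_end = 2500,
                         wavelength_step = 1,
                         darkening_strength = 0.012,
                         absorption_centers = c(1400, 1900, 2200),
                         absorption_depths = c(0.25, 0.35, 0.02),
                         absorption_sigmas = c(50, 60, 10),
                         som_linked_feature_center = 2200,
                         som_feature_depth_slope = 0.006,
                         clay_feature_center = 2200,
                         clay_feature_sigma = 25,
                         clay_feature_depth = 0.06,
                         illite_feature_center = 2220,
                         illite_feature_sigma = 15,
                         illite_feature_depth = 0.06,
                         aliphatic_feature_center = 1730,
                         aliphatic_feature_sigma = 25,
                         aliphatic_feature_depth = 0.08,
                         carbonate_feature_center = 2340,
                         carbonate_feature_sigma = 30,
                         carbonate_feature_depth = 0.10,
                         vis_chromophore_center = 500,
                         vis_chromophore_sigma = 150,
                         vis_chromophore_depth = 0.3,
                         moisture_depth_range = c(0.6, 1.4),
                         moisture_slope = 0.06,
                         baseline_tilt_sd = 0.03,
                         albedo_sd = 0.08,
                         noise_sd_multiplicative = 0.004,
                         noise_sd_additive = 0.001,
                         seed = 42L) {
  cfg <- list(
    n_samples = as.integer(n_samples), som_mean = som_mean, som_sd = som_sd,
    som_min = som_min, som_max = som_max,
    wavelength_start = wavelength_start, wavelength_end = wavelength_end,
    wavelength_step = wavelength_step,
    darkening_strength = darkening_strength,
    absorption_centers = absorption_centers,
    absorption_depths = absorption_depths,
    absorption_sigmas = absorption_sigmas,
    som_linked_feature_center = som_linked_feature_center,
    som_feature_depth_slope = som_feature_depth_slope,
    clay_feature_center = clay_feature_center,
    clay_feature_sigma = clay_feature_sigma,
    clay_feature_depth = clay_feature_depth,
    illite_feature_center = illite_feature_center,
    illite_feature_sigma = illite_feature_sigma,
    illite_feature_depth = illite_feature_depth,
    aliphatic_feature_center = aliphatic_feature_center,
    aliphatic_feature_sigma = aliphatic_feature_sigma,
    aliphatic_feature_depth = aliphatic_feature_depth,
    carbonate_feature_center = carbonate_feature_center,
    carbonate_feature_sigma = carbonate_feature_sigma,
    carbonate_feature_depth = carbonate_feature_depth,
    vis_chromophore_center = vis_chromophore_center,
    vis_chromophore_sigma = vis_chromophore_sigma,
    vis_chromophore_depth = vis_chromophore_depth,
    moisture_depth_range = moisture_depth_range,
    moisture_slope = moisture_slope,
    baseline_tilt_sd = baseline_tilt_sd,
    albedo_sd = albedo_sd,
    noise_sd_multiplicative = noise_sd_multiplicative,
    noise_sd_additive = noise_sd_additive,
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_samples < 2L) stop("n_samples must be >= 2")
  if (cfg$som_sd <= 0) stop("som_sd must be > 0 (infeasible moment match)")
  if (cfg$som_mean <= 0) stop("som_mean must be > 0")
  if (cfg$som_min >= cfg$som_max) stop("som_min must be < som_max")
  if (cfg$wavelength_start >= cfg$wavelength_end) {
    stop("wavelength_start must be < wavelength_end")
  }
  if (cfg$wavelength_step <= 0) stop("wavelength_step must be > 0")
  wl <- synth_wavelengths(cfg)
  if (any(cfg$absorption_centers < min(wl) | cfg$absorption_centers > max(wl))) {
    stop("all absorption_centers must lie within the wavelength range")
  }
  nc <- length(cfg$absorption_centers)
  if (length(cfg$absorption_depths) != nc || length(cfg$absorption_sigmas) != nc) {
    stop("absorption_depths and absorption_sigmas must match absorption_centers")
  }
  if (any(cfg$absorption_depths < 0 | cfg$absorption_depths >= 1)) {
    stop("absorption_depths must be in [0, 1)")
  }
  if (!(cfg$som_linked_feature_center %in% cfg$absorption_centers)) {
    stop("som_linked_feature_center must be one of absorption_centers")
  }
  if (cfg$noise_sd_multiplicative < 0 || cfg$noise_sd_additive < 0) {
    stop("noise parameters must be >= 0")
  }
  if (cfg$clay_feature_depth < 0 || cfg$clay_feature_depth >= 1) {
    stop("clay_feature_depth must be in [0, 1)")
  }
  if (cfg$illite_feature_depth < 0 || cfg$illite_feature_depth >= 1) {
    stop("illite_feature_depth must be in [0, 1)")
  }
  if (cfg$aliphatic_feature_depth < 0 || cfg$aliphatic_feature_depth >= 1 ||
      cfg$carbonate_feature_depth < 0 || cfg$carbonate_feature_depth >= 1) {
    stop("feature depths must be in [0, 1)")
  }
  if (cfg$vis_chromophore_depth < 0 || cfg$vis_chromophore_depth >= 1) {
    stop("vis_chromophore_depth must be in [0, 1)")
  }
  if (cfg$clay_feature_center < min(wl) || cfg$clay_feature_center > max(wl)) {
    stop("clay_feature_center must lie within the wavelength range")
  }
  if (cfg$darkening_strength < 0) stop("darkening_strength must be >= 0")
  invisible(cfg)
}

synth_wavelengths <- function(cfg) {
  seq(cfg$wavelength_start, cfg$wavelength_end, by = cfg$wavelength_step)
}

#' Generate SOM contents
#'
#' Draws SOM (g/kg) from a lognormal whose underlying mean and standard
#' deviation match \code{som_mean}/\code{som_sd} by moment matching
#' (\eqn{\sigma^2 = \log(1 + sd^2/mean^2)}, \eqn{\mu = \log(mean) - \sigma^2/2}),
#' truncated to \code{[som_min, som_max]} by rejection sampling. Reproduces
#' the positivity, right skew and heavy tail of arid-region topsoil SOM.
#'
#' @param config A [synth_config()].
#' @param seed Optional seed overriding \code{config$seed}.
#' @return Numeric vector of length \code{n_samples}, all within the bounds.
#' @export
generate_som <- function(config, seed = config$seed) {
  validate_synth_config(config)
  sigma2 <- log(1 + (config$som_sd / config$som_mean)^2)
  mu <- log(config$som_mean) - sigma2 / 2
  sdlog <- sqrt(sigma2)
  n <- config$n_samples
  with_seed(seed, {
    out <- numeric(0)
    while (length(out) < n) {
      draw <- stats::rlnorm(max(n, 32L), meanlog = mu, sdlog = sdlog)
      out <- c(out, draw[draw >= config$som_min & draw <= config$som_max])
    }
    out[seq_len(n)]
  })
}

# Weight profile of SOM darkening: ~1 across the visible (400-700 nm),
# decaying to a small NIR floor so darkening is strongest in the visible.
som_darkening_profile <- function(wl) {
  0.15 + 0.85 / (1 + exp((wl - 750) / 100))
}

# Smooth increasing base reflectance curve (bright arid soil).
base_reflectance_curve <- function(wl) {
  0.15 + 0.45 / (1 + exp(-(wl - 1000) / 350))
}

#' Generate reflectance spectra paired with SOM values
#'
#' Generative model, per sample i and wavelength w (reflectance in (0,1]):
#' \deqn{R_i(w) = B(w) \, a_i \, e^{t_i \delta(w)} \, e^{-d \cdot SOM_i \cdot v(w)}
#'   \, m_i(w) \prod_c (1 - depth_{c,i} \, e^{-(w-c)^2 / 2\sigma_c^2})}
#' where \eqn{B} is a smooth increasing base curve, \eqn{a_i} a lognormal
#' albedo factor, \eqn{t_i \delta(w)} a log-linear continuum tilt
#' (particle-size scatter), \eqn{v} the visible-band darkening profile,
#' \eqn{m_i} a moisture-driven long-wavelength continuum depression, and the
#' product holds Gaussian absorption troughs. The trough at
#' \code{som_linked_feature_center} has depth
#' \code{absorption_depths[k] + som_feature_depth_slope * SOM}; the other
#' troughs scale with a per-sample moisture latent. Multiplicative and
#' additive Gaussian noise are applied last and the result is clipped to
#' (0, 1].
#'
#' @param som Numeric vector of SOM values (g/kg), finite and positive.
#' @param config A [synth_config()].
#' @param seed Optional seed; defaults to \code{config$seed + 1} so that a
#'   dataset built from (\code{generate_som}, \code{generate_spectra}) uses
#'   two independent substreams of the one configured seed.
#' @return A [spectra_set] with \code{length(som)} rows.
#' @export
generate_spectra <- function(som, config, seed = config$seed + 1L) {
  validate_synth_config(config)
  som <- as.numeric(som)
  if (length(som) == 0L) stop("empty som vector")
  if (any(!is.finite(som)) || any(som <= 0)) stop("som must be finite and positive")
  wl <- synth_wavelengths(config)
  n <- length(som)
  nb <- length(wl)

  base <- base_reflectance_curve(wl)
  vprof <- som_darkening_profile(wl)
  delta <- (wl - mean(range(wl))) / diff(range(wl))  # tilt coordinate in [-0.5, 0.5]

  with_seed(seed, {
    albedo <- exp(stats::rnorm(n, 0, config$albedo_sd))
    tilt <- stats::rnorm(n, 0, config$baseline_tilt_sd)
    moisture <- stats::runif(n)
    clay <- stats::runif(n)
    illite <- stats::runif(n)
    aliphatic <- stats::runif(n)
    carbonate <- stats::runif(n)
    vis_chrom <- stats::runif(n)

    # n x nb brightness surface (all multiplicative, strictly positive)
    refl <- outer(albedo, base) *
      exp(outer(tilt, delta)) *
      exp(-config$darkening_strength * outer(som, vprof))

    # moisture-driven continuum depression beyond 1900 nm (linear in w)
    longw <- pmax(0, wl - 1900) / 600
    refl <- refl * (1 - config$moisture_slope * outer(moisture, longw))

    # absorption troughs
    mlo <- config$moisture_depth_range[1]
    mhi <- config$moisture_depth_range[2]
    for (k in seq_along(config$absorption_centers)) {
      ctr <- config$absorption_centers[k]
      shape <- exp(-(wl - ctr)^2 / (2 * config$absorption_sigmas[k]^2))
      if (ctr == config$som_linked_feature_center) {
        depth <- config$absorption_depths[k] + config$som_feature_depth_slope * som
      } else {
        depth <- config$absorption_depths[k] * (mlo + (mhi - mlo) * moisture)
      }
      depth <- pmin(depth, 0.95)
      refl <- refl * (1 - outer(depth, shape))
    }

    # independent clay absorption overlapping the SOM-linked feature region
    if (config$clay_feature_depth > 0) {
      cshape <- exp(-(wl - config$clay_feature_center)^2 /
                      (2 * config$clay_feature_sigma^2))
      refl <- refl * (1 - outer(config$clay_feature_depth * clay, cshape))
    }

    # independent illite-like absorption offset from the SOM feature
    if (config$illite_feature_depth > 0) {
      ishape <- exp(-(wl - config$illite_feature_center)^2 /
                      (2 * config$illite_feature_sigma^2))
      refl <- refl * (1 - outer(config$illite_feature_depth * illite, ishape))
    }

    # further independent mineral/organic bands away from the SOM feature;
    # they occupy leading principal components of real soil spectra
    if (config$aliphatic_feature_depth > 0) {
      ashape <- exp(-(wl - config$aliphatic_feature_center)^2 /
                      (2 * config$aliphatic_feature_sigma^2))
      refl <- refl * (1 - outer(config$aliphatic_feature_depth * aliphatic, ashape))
    }
    if (config$carbonate_feature_depth > 0) {
      kshape <- exp(-(wl - config$carbonate_feature_center)^2 /
                      (2 * config$carbonate_feature_sigma^2))
      refl <- refl * (1 - outer(config$carbonate_feature_depth * carbonate, kshape))
    }

    # independent visible chromophore (iron oxides)
    if (config$vis_chromophore_depth > 0) {
      vshape <- exp(-(wl - config$vis_chromophore_center)^2 /
                      (2 * config$vis_chromophore_sigma^2))
      refl <- refl * (1 - outer(config$vis_chromophore_depth * vis_chrom, vshape))
    }

    if (config$noise_sd_multiplicative > 0) {
      refl <- refl * (1 + matrix(stats::rnorm(n * nb, 0, config$noise_sd_multiplicative),
                                 n, nb))
    }
    if (config$noise_sd_additive > 0) {
      refl <- refl + matrix(stats::rnorm(n * nb, 0, config$noise_sd_additive), n, nb)
    }
    refl <- pmin(pmax(refl, 1e-6), 1)
    spectra_set(wl, refl)
  })
}

#' Generate a complete synthetic soil dataset
#'
#' Convenience wrapper: [generate_som()] then [generate_spectra()], both
#' seeded from \code{config$seed} (SOM uses \code{seed}, spectra
#' \code{seed + 1}).
#'
#' @inheritParams generate_som
#' @return A [soil_dataset].
#' @export
generate_dataset <- function(config = synth_config(), seed = config$seed) {
  som <- generate_som(config, seed = seed)
  sp <- generate_spectra(som, config, seed = seed + 1L)
  soil_dataset(som, sp)
}
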