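#' Default sieve fractions
#'
#' The seven particle-size classes used throughout the package, as a tibble
#' of sieve bounds in micrometres with a representative diameter (arithmetic
#' mean of the bounds; the open "<90" class uses bounds 0-90, representative
#' 45).
#'
#' @return A tibble with columns `label`, `lower_um`, `upper_um`,
#'   `representative_um`, ordered from coarsest to finest.
#' @export
particle_fractions <- function() {
  tibble::tibble(
    label = c("355-850", "250-355", "180-250", "150-180", "125-150",
              "90-125", "<90"),
    lower_um = c(355, 250, 180, 150, 125, 90, 0),
    upper_um = c(850, 355, 250, 180, 150, 125, 90)
  ) |>
    dplyr::mutate(representative_um = (.data$lower_um + .data$upper_um) / 2)
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic diffuse-reflectance generator. The
#' defaults emulate the study design the package targets: 30 base powder
#' samples (10 batches x 3 representative samples), each sieved into 7
#' particle-size fractions and measured in triplicate over 780-2500 nm;
#' analyte content around 1.5 mg/g with batch-to-batch spread 0.5 mg/g;
#' scatter inversely proportional to particle diameter; small additive
#' (per-wavelength) and multiplicative (per-replicate) reflectance noise; a
#' 1.5 % relative error on the chromatographic reference values.
#'
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @param n_base_samples Base powder samples before sieving (default 30).
#' @param fractions Tibble of sieve fractions as from [particle_fractions()].
#' @param n_replicates Replicate spectra per sample, averaged after
#'   log-transform (default 3).
#' @param wavelength_lo,wavelength_hi,wavelength_step Grid in nm (defaults
#'   780, 2500, 2).
#' @param concentration_mean,concentration_sd,concentration_min Analyte
#'   content distribution in mg/g: normal, truncated below at
#'   `concentration_min` (defaults 1.5, 0.5, 0.2).
#' @param analyte_peaks Data frame of Gaussian absorption bands of the
#'   analyte with columns `center_nm`, `width_nm`, `height`; defaults place
#'   bands in the second-overtone, first-combination-overtone and
#'   combination regions (1200, 1700, 2270 nm).
#' @param background_base,background_slope,background_power Matrix background
#'   absorption: `base + slope * ((lambda - lo)/(hi - lo))^power`, a smooth
#'   positive spectrum rising toward long wavelengths.
#' @param reference_scatter,reference_diameter Scatter coefficient (same
#'   units as k) at the reference diameter in micrometres; defaults 1 at
#'   137.5 um, the representative diameter of the 125-150 um fraction.
#' @param additive_noise_sd Per-wavelength reflectance noise SD (default
#'   5e-4, already reflecting 64-scan averaging).
#' @param multiplicative_noise_sd Per-replicate multiplicative reflectance
#'   error SD (default 2e-3), the packing/gain variation that scatter
#'   correction targets.
#' @param hplc_cv Relative SD of the reference-value error (default 0.015).
#' @return A `kmnir_sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_base_samples = 30L,
                       fractions = particle_fractions(),
                       n_replicates = 3L,
                       wavelength_lo = 780, wavelength_hi = 2500,
                       wavelength_step = 2,
                       concentration_mean = 1.5, concentration_sd = 0.5,
                       concentration_min = 0.2,
                       analyte_peaks = default_analyte_peaks(),
                       background_base = 0.04, background_slope = 0.4,
                       background_power = 1.5,
                       reference_scatter = 1, reference_diameter = 137.5,
                       additive_noise_sd = 5e-4,
                       multiplicative_noise_sd = 2e-3,
                       hplc_cv = 0.015) {
  stopifnot(
    wavelength_step > 0, wavelength_lo < wavelength_hi,
    n_replicates >= 1, n_base_samples >= 1,
    additive_noise_sd >= 0, multiplicative_noise_sd >= 0, hplc_cv >= 0,
    concentration_sd >= 0, concentration_min > 0,
    reference_scatter > 0, reference_diameter > 0,
    all(fractions$lower_um >= 0),
    all(fractions$lower_um < fractions$upper_um),
    all(fractions$representative_um >= fractions$lower_um),
    all(fractions$representative_um <= fractions$upper_um)
  )
  structure(
    list(
      seed = as.integer(seed), n_base_samples = as.integer(n_base_samples),
      fractions = fractions, n_replicates = as.integer(n_replicates),
      wavelength_lo = wavelength_lo, wavelength_hi = wavelength_hi,
      wavelength_step = wavelength_step,
      concentration_mean = concentration_mean,
      concentration_sd = concentration_sd,
      concentration_min = concentration_min,
      analyte_peaks = analyte_peaks,
      background_base = background_base,
      background_slope = background_slope,
      background_power = background_power,
      reference_scatter = reference_scatter,
      reference_diameter = reference_diameter,
      additive_noise_sd = additive_noise_sd,
      multiplicative_noise_sd = multiplicative_noise_sd,
      hplc_cv = hplc_cv
    ),
    class = "kmnir_sim_config"
  )
}

#' @rdname sim_config
#' @export
default_analyte_peaks <- function() {
  tibble::tibble(
    center_nm = c(1200, 1700, 2270),
    width_nm = c(60, 80, 90),
    height = c(0.06, 0.10, 0.15)
  )
}

config_wavelengths <- function(config) {
  seq(config$wavelength_lo, config$wavelength_hi,
      by = config$wavelength_step)
}

#' Analyte absorptivity and matrix background profiles
#'
#' Builds the two wavelength profiles behind the generator's absorption
#' coefficient \eqn{k(\lambda) = c \cdot \alpha(\lambda) + b(\lambda)}: the
#' analyte absorptivity \eqn{\alpha} as a sum of the configured Gaussian
#' bands (per mg/g of analyte) and the matrix background \eqn{b} as a smooth
#' positive spectrum rising toward long wavelengths. Both are nonnegative
#' everywhere.
#'
#' @param config A [sim_config()] object.
#' @return A tibble with columns `wavelength`, `absorptivity`, `background`.
#' @export
make_absorptivity_profile <- function(config) {
  stopifnot(inherits(config, "kmnir_sim_config"))
  wl <- config_wavelengths(config)
  pk <- config$analyte_peaks
  absorptivity <- rep(0, length(wl))
  if (!is.null(pk) && nrow(pk) > 0L) {
    outside <- pk$center_nm < min(wl) | pk$center_nm > max(wl)
    if (any(outside)) {
      warning(sprintf("%d analyte peak(s) fall outside the wavelength grid",
                      sum(outside)), call. = FALSE)
    }
    for (i in seq_len(nrow(pk))) {
      absorptivity <- absorptivity +
        pk$height[i] * exp(-0.5 * ((wl - pk$center_nm[i]) / pk$width_nm[i])^2)
    }
  }
  frac <- (wl - config$wavelength_lo) /
    (config$wavelength_hi - config$wavelength_lo)
  background <- config$background_base +
    config$background_slope * frac^config$background_power
  tibble::tibble(wavelength = wl, absorptivity = absorptivity,
                 background = background)
}

#' Simulate a particle-size-resolved diffuse reflectance dataset
#'
#' Draws analyte contents for the base samples, computes each fraction's
#' Kubelka-Munk spectrum, adds replicate measurement noise on the
#' reflectance scale, averages the replicate absorbances, and attaches noisy
#' chromatographic reference values. Per sample and wavelength:
#' \eqn{k = c\,\alpha(\lambda) + b(\lambda)}, \eqn{s} from the \eqn{1/d}
#' law, \eqn{R_\infty} by inverting the remission function, then per
#' replicate \eqn{R = R_\infty (1 + \epsilon_{mult}) + \epsilon_{add}}
#' clipped to \eqn{(10^{-6}, 1]} and \eqn{A = -\log_{10} R}. Everything is
#' reproducible from `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements
#'   \describe{
#'     \item{spectra}{spectra tibble: `sample_id`, `batch`, `fraction`, then
#'       one absorbance column per wavelength (replicate mean).}
#'     \item{references}{tibble `sample_id`, `content` (mg/g, with assay
#'       error).}
#'     \item{truth}{tibble `sample_id`, `batch`, `fraction`,
#'       `representative_um`, `true_concentration`.}
#'     \item{k, s}{samples x wavelengths matrices of the generating
#'       absorption and scatter coefficients.}
#'     \item{profile}{the [make_absorptivity_profile()] tibble.}
#'   }
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "kmnir_sim_config"))
  withr_seed(config$seed, {
    concentrations <- draw_truncated_normal(
      config$n_base_samples, config$concentration_mean,
      config$concentration_sd, config$concentration_min
    )
    build_dataset(config, concentrations)
  })
}

#' Pure-scatter fixture dataset
#'
#' All samples share one analyte concentration, so fraction membership
#' (hence the scatter coefficient) and measurement noise are the only
#' sources of spectral variation. This isolates the particle-size effect
#' that scatter-correction preprocessing is meant to remove.
#'
#' @param config A [sim_config()] object.
#' @param concentration The shared analyte content in mg/g (default the
#'   configured mean).
#' @return Same structure as [simulate_dataset()].
#' @export
pure_scatter_dataset <- function(config = sim_config(),
                                 concentration = NULL) {
  stopifnot(inherits(config, "kmnir_sim_config"))
  conc <- concentration %||% config$concentration_mean
  withr_seed(config$seed, {
    build_dataset(config, rep(conc, config$n_base_samples))
  })
}

build_dataset <- function(config, concentrations) {
  wl <- config_wavelengths(config)
  profile <- make_absorptivity_profile(config)
  fr <- config$fractions
  n_base <- config$n_base_samples
  n_frac <- nrow(fr)
  n <- n_base * n_frac
  batch <- rep(rep(seq_len(ceiling(n_base / 3)), each = 3L)[seq_len(n_base)],
               times = n_frac)
  base_idx <- rep(seq_len(n_base), times = n_frac)
  frac_idx <- rep(seq_len(n_frac), each = n_base)
  s_by_frac <- scatter_from_particle_size(
    fr$representative_um, config$reference_scatter, config$reference_diameter
  )
  k_mat <- outer(concentrations[base_idx], profile$absorptivity) +
    matrix(profile$background, n, length(wl), byrow = TRUE)
  s_mat <- matrix(s_by_frac[frac_idx], n, length(wl))
  r_inf <- invert_remission(k_mat / s_mat)
  a_mat <- matrix(0, n, length(wl))
  for (r in seq_len(config$n_replicates)) {
    eps_mult <- stats::rnorm(n, 0, config$multiplicative_noise_sd)
    eps_add <- matrix(stats::rnorm(n * length(wl), 0,
                                   config$additive_noise_sd), n, length(wl))
    r_meas <- r_inf * (1 + eps_mult) + eps_add
    r_meas <- pmin(pmax(r_meas, 1e-6), 1)
    a_mat <- a_mat - log10(r_meas)
  }
  a_mat <- a_mat / config$n_replicates
  sample_id <- sprintf("S%02d_%s", base_idx, fr$label[frac_idx])
  ref_err <- stats::rnorm(n, 0, config$hplc_cv)
  true_conc <- concentrations[base_idx]
  meta <- tibble::tibble(
    sample_id = sample_id, batch = batch, fraction = fr$label[frac_idx]
  )
  rownames(k_mat) <- sample_id
  rownames(s_mat) <- sample_id
  list(
    spectra = as_spectra_tibble(a_mat, wl, meta),
    references = tibble::tibble(
      sample_id = sample_id, content = true_conc * (1 + ref_err)
    ),
    truth = dplyr::mutate(meta,
                          representative_um = fr$representative_um[frac_idx],
                          true_concentration = true_conc),
    k = k_mat, s = s_mat, profile = profile
  )
}

draw_truncated_normal <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(pmax(mean, lower), n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      v <- stats::rnorm(1, mean, sd)
      if (v >= lower) break
    }
    out[i] <- v
  }
  out
}

# run code under a local RNG state without disturbing the caller's
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
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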