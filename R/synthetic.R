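#' Gaussian band profile
#'
#' Evaluates a Gaussian band parameterized by peak height and full width at
#' half maximum (FWHM) on a wavenumber grid:
#' `height * exp(-4 ln2 (x - center)^2 / fwhm^2)`. The integrated band area
#' in closed form is `height * fwhm * sqrt(pi / (4 ln 2))`
#' (approximately `1.06447 * height * fwhm`).
#'
#' @param center band center (cm^-1).
#' @param fwhm full width at half maximum (cm^-1), > 0.
#' @param height peak height (absorbance a.u.).
#' @param wavenumber wavenumber grid to evaluate on.
#' @return Numeric vector of band intensities, same length as `wavenumber`.
#' @export
gaussian_band <- function(center, fwhm, height, wavenumber) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  height * exp(-4 * log(2) * ((wavenumber - center) / fwhm)^2)
}

# Deterministic per-spectrum seed stream: spectrum i of a cohort seeded with
# `seed` uses (seed * 100003 + i) mod (2^31 - 1), keeping seeds in integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 100003 + i) %% 2147483647)
}

# Expand a preset into per-band generating parameters (no randomness):
# lipid/ester/amide-II bands keep their preset heights; amide I component
# heights are derived from area = total * fraction via area/(fwhm * 1.06447).
preset_band_params <- function(preset) {
  bands <- band_table()
  bands <- bands[bands$name %in% c(names(preset$band_heights),
                                   names(preset$amide_area_fractions)), , drop = FALSE]
  h <- numeric(nrow(bands))
  names(h) <- bands$name
  h[names(preset$band_heights)] <- preset$band_heights
  amide <- names(preset$amide_area_fractions)
  areas <- preset$amide_area_total * preset$amide_area_fractions
  h[amide] <- areas / (bands$fwhm[match(amide, bands$name)] * GAUSS_AREA_FACTOR)
  data.frame(name = bands$name, center = bands$center, fwhm = bands$fwhm,
             height = as.numeric(h[bands$name]), stringsAsFactors = FALSE)
}

# Smooth instrument/scattering background: linear in wavenumber by default.
baseline_curve <- function(preset, wavenumber) {
  preset$baseline_coeffs[["intercept"]] +
    preset$baseline_coeffs[["slope"]] * (wavenumber - 1000)
}

#' Generate one synthetic absorbance spectrum
#'
#' Draws a spectrum as baseline + sum of Gaussian bands + i.i.d. Gaussian
#' noise. Band heights are perturbed by a mean-preserving log-normal factor
#' with coefficient of variation `height_cv` (so cohort-mean heights equal the
#' preset values and heights stay positive); band centers are jittered by a
#' Gaussian with SD `center_jitter_sd`. Amide I component heights are derived
#' from the preset's total amide area and area fractions before perturbation.
#'
#' @param preset a `condition_preset`.
#' @param seed integer seed; the draw is fully reproducible per seed.
#' @param spectrum_id identifier for the generated spectrum.
#' @param wavenumber grid to generate on (default: the 6224-point 4000-1000
#'   cm^-1 acquisition grid).
#' @return An `ftir_spectrum` carrying the preset's condition label.
#' @export
generate_spectrum <- function(preset, seed, spectrum_id = "sim_001",
                              wavenumber = default_grid()) {
  validate_preset(preset)
  wavenumber <- validate_grid(wavenumber)  # canonical decreasing copy
  pars <- preset_band_params(preset)
  set.seed(as.integer(seed))
  n_bands <- nrow(pars)
  if (preset$height_cv > 0) {
    sdlog <- sqrt(log(1 + preset$height_cv^2))
    fac <- rlnorm(n_bands, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else {
    fac <- rep(1, n_bands)
  }
  jit <- rnorm(n_bands, 0, preset$center_jitter_sd)
  y <- baseline_curve(preset, wavenumber)
  for (i in seq_len(n_bands)) {
    y <- y + gaussian_band(pars$center[i] + jit[i], pars$fwhm[i],
                           pars$height[i] * fac[i], wavenumber)
  }
  if (preset$noise_sd > 0) y <- y + rnorm(length(wavenumber), 0, preset$noise_sd)
  new_spectrum(wavenumber, y, id = spectrum_id, condition = preset$condition)
}

#' Generate a condition cohort
#'
#' Generates `n` independent spectra from one preset. Each spectrum uses a
#' seed derived deterministically from the cohort seed, so cohorts are
#' reproducible across runs and platforms.
#'
#' @param preset a `condition_preset`.
#' @param n number of spectra (>= 1).
#' @param seed cohort seed.
#' @param wavenumber grid to generate on.
#' @return An `ftir_spectra_set` with all rows labeled by the preset condition.
#' @export
generate_cohort <- function(preset, n, seed, wavenumber = default_grid()) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("n must be a positive count", call. = FALSE)
  }
  n <- as.integer(n)
  validate_preset(preset)
  ids <- sprintf("%s_%03d", preset$condition, seq_len(n))
  mat <- matrix(NA_real_, nrow = n, ncol = length(wavenumber))
  for (i in seq_len(n)) {
    sp <- generate_spectrum(preset, derive_seed(seed, i), ids[i], wavenumber)
    mat[i, ] <- sp$absorbance
    if (i == 1L) wavenumber <- sp$wavenumber  # canonical order from first draw
  }
  new_spectra_set(wavenumber, mat,
                  data.frame(spectrum_id = ids, condition = preset$condition,
                             stringsAsFactors = FALSE))
}

#' Generate the default three-condition study
#'
#' Convenience wrapper producing the full synthetic study: untreated,
#' steatotic, and Ex-4-treated cohorts (70/80/80 spectra by default) on a
#' common grid, combined into one set.
#'
#' @param n named integer vector of cohort sizes.
#' @param seed master seed; per-cohort seeds are derived from it.
#' @param ... passed to [condition_preset()] (e.g. variability overrides).
#' @return An `ftir_spectra_set` with 230 spectra under the defaults.
#' @export
generate_study <- function(n = c(untreated = 70, steatotic = 80, ex4 = 80),
                           seed = 1, ...) {
  conds <- names(n)
  if (is.null(conds) || !all(conds %in% c("untreated", "steatotic", "ex4"))) {
    stop("n must be a named vector over untreated/steatotic/ex4", call. = FALSE)
  }
  sets <- lapply(seq_along(conds), function(k) {
    generate_cohort(condition_preset(conds[k], ...), n[[k]], derive_seed(seed, k))
  })
  do.call(bind_spectra_sets, sets)
}
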