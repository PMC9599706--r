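#' Band table and condition presets
#'
#' Band assignments (centers, widths, fit bounds) and the generating
#' intensities for the three experimental conditions live in a versioned
#' preset file shipped with the package (`inst/extdata/presets.yaml`).
#'
#' @name presets
NULL

.preset_env <- new.env(parent = emptyenv())

#' Load the packaged preset file
#'
#' @param path optional path to an alternative preset file in the same schema.
#' @return Nested list mirroring the YAML structure.
#' @export
presets <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.preset_env$cache)) return(.preset_env$cache)
    path <- system.file("extdata", "presets.yaml", package = "ftirsteat", mustWork = TRUE)
    p <- yaml::read_yaml(path)
    .preset_env$cache <- p
    return(p)
  }
  yaml::read_yaml(path)
}

#' Band definition table
#'
#' One row per named Gaussian band: center, FWHM, fit bounds, spectral-window
#' group, and chemical assignment. Center bounds are center +/- 6 cm^-1 and
#' FWHM bounds `[8, 50]` cm^-1 by default; the +/-6 windows of neighbouring
#' bands are disjoint (or touching), so band identities cannot cross during
#' refinement.
#'
#' @param group optional filter: one of `"lipid"`, `"ester"`, `"amide_i"`,
#'   `"amide_ii"`, or `NULL` for all bands.
#' @return data.frame with columns `name`, `center`, `fwhm`, `center_lo`,
#'   `center_hi`, `fwhm_lo`, `fwhm_hi`, `group`, `assignment`.
#' @export
band_table <- function(group = NULL) {
  p <- presets()
  hw <- p$fit_defaults$center_bound_halfwidth
  fb <- p$fit_defaults$fwhm_bounds
  rows <- lapply(names(p$bands), function(nm) {
    b <- p$bands[[nm]]
    data.frame(name = nm, center = b$center, fwhm = b$fwhm,
               center_lo = b$center - hw, center_hi = b$center + hw,
               fwhm_lo = fb[[1]], fwhm_hi = fb[[2]],
               group = b$group, assignment = b$assignment,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(group)) {
    out <- out[out$group %in% group, , drop = FALSE]
    if (nrow(out) == 0L) stop("no bands in group ", group, call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Deconvolution model for a spectral window
#'
#' A band model pairs a wavenumber window with the ordered band definitions
#' fitted inside it. The packaged windows are lipid C-H stretching
#' (2750-3100 cm^-1, five bands), ester carbonyl (1700-1780), amide I
#' (1600-1700, five secondary-structure components), and amide II
#' (1510-1580, one band, intensity reporting only).
#'
#' @param window one of `"lipid"`, `"ester"`, `"amide_i"`, `"amide_ii"`.
#' @return An object of class `band_model`: the band table for the window
#'   with the window interval attached as attribute `window` (`c(lo, hi)`).
#' @export
band_model <- function(window = c("lipid", "ester", "amide_i", "amide_ii")) {
  window <- match.arg(window)
  p <- presets()
  bands <- band_table(group = window)
  bands <- bands[order(-bands$center), , drop = FALSE]
  rownames(bands) <- NULL
  w <- as.numeric(p$windows[[window]])
  if (any(bands$center <= w[1]) || any(bands$center >= w[2])) {
    stop("band centers fall outside the model window", call. = FALSE)
  }
  structure(bands, window = sort(w),
            baseline_support = sort(as.numeric(p$baseline_support[[window]])),
            window_name = window, class = c("band_model", "data.frame"))
}

#' Condition preset for the synthetic generator
#'
#' Returns the generating parameters for one experimental condition:
#' band heights for the lipid, ester, and amide II bands; total amide I area
#' and its secondary-structure fractions; baseline coefficients; and the
#' variability/noise defaults (log-normal height CV, Gaussian center jitter,
#' additive noise SD).
#'
#' @param condition `"untreated"`, `"steatotic"`, or `"ex4"`.
#' @param height_cv,center_jitter_sd,noise_sd optional overrides of the
#'   packaged variability defaults (set all three to 0 for a deterministic,
#'   noise-free template).
#' @return A validated list of class `condition_preset`.
#' @export
condition_preset <- function(condition = c("untreated", "steatotic", "ex4"),
                             height_cv = NULL, center_jitter_sd = NULL,
                             noise_sd = NULL) {
  condition <- match.arg(condition)
  p <- presets()
  cond <- p$conditions[[condition]]
  pre <- list(
    condition = condition,
    band_heights = unlist(cond$band_heights),
    amide_area_total = cond$amide_area_total,
    amide_area_fractions = unlist(cond$amide_area_fractions),
    baseline_coeffs = c(intercept = p$baseline$intercept, slope = p$baseline$slope),
    height_cv = height_cv %||% p$variability$height_cv,
    center_jitter_sd = center_jitter_sd %||% p$variability$center_jitter_sd,
    noise_sd = noise_sd %||% p$variability$noise_sd
  )
  class(pre) <- "condition_preset"
  validate_preset(pre)
  pre
}

#' Validate a condition preset
#'
#' Rejects presets whose amide fractions do not sum to 1 (tolerance 1e-9) or
#' with negative heights, areas, variability, or noise.
#'
#' @param preset a `condition_preset` (or a bare list in the same shape).
#' @return The preset, invisibly.
#' @export
validate_preset <- function(preset) {
  need <- c("condition", "band_heights", "amide_area_total",
            "amide_area_fractions", "baseline_coeffs",
            "height_cv", "center_jitter_sd", "noise_sd")
  miss <- setdiff(need, names(preset))
  if (length(miss)) stop("preset is missing fields: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(preset$band_heights < 0)) stop("preset band heights must be >= 0", call. = FALSE)
  if (preset$amide_area_total < 0) stop("amide_area_total must be >= 0", call. = FALSE)
  fr <- preset$amide_area_fractions
  if (any(fr < 0)) stop("amide area fractions must be >= 0", call. = FALSE)
  if (abs(sum(fr) - 1) > 1e-9) {
    stop("amide area fractions must sum to 1 (got ", format(sum(fr), digits = 12), ")",
         call. = FALSE)
  }
  if (preset$height_cv < 0 || preset$center_jitter_sd < 0 || preset$noise_sd < 0) {
    stop("variability and noise parameters must be >= 0", call. = FALSE)
  }
  known <- band_table()$name
  bad <- setdiff(c(names(preset$band_heights), names(fr)), known)
  if (length(bad)) stop("unknown band names in preset: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(preset)
}
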