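#' Spectral preprocessing
#'
#' The analysis assumes a fixed preprocessing order: area normalization of the
#' full spectrum, then baseline correction of the analysis window, then
#' deconvolution. All downstream ratio metrics are invariant to global scaling
#' of the raw input because normalization removes the scale exactly.
#'
#' @name preprocessing
NULL

# Trapezoidal area on a (possibly decreasing) wavenumber grid, taken over
# increasing wavenumber so a positive spectrum has positive area.
trapz_area <- function(wavenumber, y) {
  o <- order(wavenumber)
  pracma::trapz(wavenumber[o], y[o])
}

#' Area-normalize a spectrum
#'
#' Divides the absorbance by the trapezoidal area under the full spectrum, so
#' the normalized trace integrates to exactly 1 over its grid. Shape is
#' preserved (output proportional to input).
#'
#' @param s an `ftir_spectrum`.
#' @return The normalized `ftir_spectrum`.
#' @export
area_normalize <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  a <- trapz_area(s$wavenumber, s$absorbance)
  if (!is.finite(a) || a <= 0) {
    stop("cannot area-normalize: total spectral area is ", format(a),
         " (pathological spectrum)", call. = FALSE)
  }
  s$absorbance <- s$absorbance / a
  s
}

#' @rdname area_normalize
#' @param set an `ftir_spectra_set`; each row is normalized independently.
#' @export
area_normalize_set <- function(set) {
  stopifnot(inherits(set, "ftir_spectra_set"))
  for (i in seq_len(nrow(set$absorbance))) {
    a <- trapz_area(set$wavenumber, set$absorbance[i, ])
    if (!is.finite(a) || a <= 0) {
      stop("cannot area-normalize spectrum ", set$metadata$spectrum_id[i],
           ": total area is ", format(a), call. = FALSE)
    }
    set$absorbance[i, ] <- set$absorbance[i, ] / a
  }
  set
}

# Lower convex hull (Andrew monotone chain) of points sorted by increasing x.
# Returns indices of hull vertices; the hull interpolates the baseline.
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(n)
  k <- 0L
  for (i in seq_len(n)) {
    while (k >= 2L) {
      a <- hull[k - 1L]; b <- hull[k]
      # pop b if it lies on or above segment a->i (cross product <= 0)
      cross <- (x[b] - x[a]) * (y[i] - y[a]) - (y[b] - y[a]) * (x[i] - x[a])
      if (cross <= 0) k <- k - 1L else break
    }
    k <- k + 1L
    hull[k] <- i
  }
  hull[seq_len(k)]
}

#' Rubberband (convex-hull) baseline correction
#'
#' Estimates the baseline of a spectrum segment as the lower convex hull of
#' its (wavenumber, absorbance) points and subtracts it. The corrected
#' spectrum is zero at the hull touch points and non-negative up to numerical
#' round-off; correcting twice equals correcting once. Intended to be applied
#' per analysis window, not to the full trace, so the hull anchors on the
#' quiet edges of the window rather than on unrelated bands.
#'
#' @param s an `ftir_spectrum` (typically already windowed).
#' @return The baseline-corrected `ftir_spectrum`.
#' @export
baseline_rubberband <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  x <- rev(s$wavenumber)      # ascending for the hull walk
  y <- rev(s$absorbance)
  idx <- lower_hull_idx(x, y)
  base <- approx(x[idx], y[idx], xout = x, rule = 2)$y
  s$absorbance <- rev(y - base)
  s
}

#' Polynomial baseline correction
#'
#' Fits a least-squares polynomial of the given degree to anchor windows --
#' by default the flat regions 3900-3700, 2700-2000, and 1000-980 cm^-1
#' (intersected with the grid) -- and subtracts it. The corrected trace is
#' then shifted so its minimum over the anchor points is zero, making the
#' result comparable with the rubberband contract (>= 0 at anchors).
#'
#' @param s an `ftir_spectrum`.
#' @param degree polynomial degree (>= 0).
#' @param anchors list of `c(lo, hi)` wavenumber intervals used as baseline
#'   anchor windows.
#' @return The corrected `ftir_spectrum`.
#' @export
baseline_polynomial <- function(s, degree = 1,
                                anchors = list(c(3700, 3900), c(2000, 2700), c(980, 1000))) {
  stopifnot(inherits(s, "ftir_spectrum"), degree >= 0)
  w <- s$wavenumber
  sel <- Reduce(`|`, lapply(anchors, function(a) w >= a[1] & w <= a[2]))
  if (sum(sel) < degree + 1) {
    # windowed spectrum with no named anchor region inside: anchor on the
    # outer 10% of the window at each edge
    span <- diff(range(w))
    sel <- w <= min(w) + 0.1 * span | w >= max(w) - 0.1 * span
  }
  if (sum(sel) < degree + 1) {
    stop("not enough anchor points inside the grid for degree ", degree, call. = FALSE)
  }
  X <- outer(w[sel], 0:degree, `^`)
  beta <- qr.solve(X, s$absorbance[sel])
  base <- outer(w, 0:degree, `^`) %*% beta
  corrected <- s$absorbance - as.numeric(base)
  corrected <- corrected - min(corrected[sel])
  s$absorbance <- corrected
  s
}

#' Baseline-correct with a named method
#'
#' @param s an `ftir_spectrum`.
#' @param method `"rubberband"` (default), `"polynomial"`, or `"none"`.
#' @param ... passed to the method function.
#' @return The corrected `ftir_spectrum`.
#' @export
baseline_correct <- function(s, method = c("rubberband", "polynomial", "none"), ...) {
  method <- match.arg(method)
  switch(method,
         rubberband = baseline_rubberband(s),
         polynomial = baseline_polynomial(s, ...),
         none = s)
}

#' Extract a wavenumber region
#'
#' Selects the half-closed window `[lo, hi)` by wavenumber value (inclusive
#' of `lo`, exclusive of `hi`); grid spacing and ordering are unchanged. Use
#' an `hi` beyond the grid maximum to keep the full span.
#'
#' @param s an `ftir_spectrum`.
#' @param lo,hi window bounds in cm^-1, `lo < hi`.
#' @return The windowed `ftir_spectrum`.
#' @export
extract_region <- function(s, lo, hi) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (!(lo < hi)) stop("extract_region requires lo < hi", call. = FALSE)
  sel <- s$wavenumber >= lo & s$wavenumber < hi
  if (!any(sel)) stop("selection [", lo, ", ", hi, ") does not overlap the grid", call. = FALSE)
  new_spectrum(s$wavenumber[sel], s$absorbance[sel], id = s$id, condition = s$condition)
}

#' @rdname extract_region
#' @param set an `ftir_spectra_set`.
#' @export
extract_region_set <- function(set, lo, hi) {
  stopifnot(inherits(set, "ftir_spectra_set"))
  if (!(lo < hi)) stop("extract_region requires lo < hi", call. = FALSE)
  sel <- set$wavenumber >= lo & set$wavenumber < hi
  if (!any(sel)) stop("selection [", lo, ", ", hi, ") does not overlap the grid", call. = FALSE)
  new_spectra_set(set$wavenumber[sel], set$absorbance[, sel, drop = FALSE], set$metadata)
}

#' Window + baseline for one analysis region
#'
#' Convenience composition used throughout the pipeline: baseline-correct the
#' model's baseline-support region (a window whose edges sit in quiet gaps
#' between band groups, so the rubberband hull anchors on background rather
#' than on the flank of a band), then cut out the fit window.
#'
#' @param s an `ftir_spectrum` (full grid, typically area-normalized).
#' @param model a `band_model` whose window to prepare.
#' @param baseline baseline method (see [baseline_correct()]).
#' @return The windowed, baseline-corrected `ftir_spectrum`.
#' @export
prepare_window <- function(s, model, baseline = "rubberband") {
  w <- attr(model, "window")
  sup <- attr(model, "baseline_support") %||% w
  corrected <- baseline_correct(extract_region(s, sup[1], sup[2]), method = baseline)
  extract_region(corrected, w[1], w[2])
}
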