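#' Wavenumber grids and spectrum containers
#'
#' Spectra are stored on a common, evenly spaced wavenumber grid. The package
#' convention is decreasing wavenumber order (standard FTIR presentation,
#' high to low cm^-1); constructors accept either order and canonicalize.
#'
#' @name spectra-containers
NULL

#' Default acquisition grid
#'
#' The default grid spans 4000 to 1000 cm^-1 with 6224 points (spacing
#' 3000/6223 cm^-1), stored in decreasing order.
#'
#' @return Numeric vector of wavenumbers, decreasing.
#' @export
default_grid <- function() {
  g <- presets()$grid
  seq(g$max, g$min, length.out = g$n_points)
}

#' Validate a wavenumber grid
#'
#' Checks that the grid is numeric, finite, strictly monotone, and evenly
#' spaced to within `tol` relative tolerance.
#'
#' @param wavenumber numeric vector of wavenumbers (cm^-1).
#' @param tol relative tolerance on spacing constancy.
#' @return The grid, invisibly, in canonical (decreasing) order.
#' @export
validate_grid <- function(wavenumber, tol = 1e-9) {
  if (!is.numeric(wavenumber) || length(wavenumber) < 2L) {
    stop("grid must be a numeric vector with at least two wavenumbers", call. = FALSE)
  }
  if (!all(is.finite(wavenumber))) stop("grid contains non-finite wavenumbers", call. = FALSE)
  d <- diff(wavenumber)
  if (!(all(d > 0) || all(d < 0))) {
    stop("grid is not strictly monotone in wavenumber", call. = FALSE)
  }
  spacing <- mean(d)
  if (max(abs(d - spacing)) > tol * abs(spacing)) {
    stop("grid spacing is not constant to within tolerance", call. = FALSE)
  }
  inv <- if (d[1] > 0) rev(wavenumber) else wavenumber
  invisible(inv)
}

#' Construct a single spectrum
#'
#' @param wavenumber wavenumber grid (cm^-1), either order.
#' @param absorbance absorbance values (a.u.), same length as `wavenumber`.
#' @param id spectrum identifier.
#' @param condition optional condition label (`NA` if unassigned).
#' @return An object of class `ftir_spectrum`: a list with elements
#'   `wavenumber` (decreasing), `absorbance`, `id`, `condition`.
#' @export
new_spectrum <- function(wavenumber, absorbance, id = "s1", condition = NA_character_) {
  validate_grid(wavenumber)
  if (length(absorbance) != length(wavenumber)) {
    stop("absorbance length does not match grid length", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) stop("absorbance contains non-finite values", call. = FALSE)
  if (wavenumber[1] < wavenumber[length(wavenumber)]) {
    wavenumber <- rev(wavenumber)
    absorbance <- rev(absorbance)
  }
  structure(
    list(wavenumber = as.numeric(wavenumber), absorbance = as.numeric(absorbance),
         id = as.character(id), condition = as.character(condition)),
    class = "ftir_spectrum"
  )
}

#' Construct a grid-aligned spectra collection
#'
#' @param wavenumber shared wavenumber grid.
#' @param absorbance numeric matrix, one row per spectrum, `length(wavenumber)`
#'   columns.
#' @param metadata data.frame with columns `spectrum_id` and `condition`,
#'   one row per spectrum (row order matches the matrix).
#' @return An object of class `ftir_spectra_set`.
#' @export
new_spectra_set <- function(wavenumber, absorbance, metadata) {
  validate_grid(wavenumber)
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavenumber)) {
    stop("absorbance matrix has ", ncol(absorbance), " columns but grid has ",
         length(wavenumber), " points", call. = FALSE)
  }
  if (!all(is.finite(absorbance))) stop("absorbance contains non-finite values", call. = FALSE)
  if (!is.data.frame(metadata) || !all(c("spectrum_id", "condition") %in% names(metadata))) {
    stop("metadata must be a data.frame with columns spectrum_id and condition", call. = FALSE)
  }
  if (nrow(metadata) != nrow(absorbance)) {
    stop("metadata has ", nrow(metadata), " rows but matrix has ",
         nrow(absorbance), " spectra", call. = FALSE)
  }
  if (anyDuplicated(metadata$spectrum_id)) {
    stop("duplicate spectrum ids in metadata", call. = FALSE)
  }
  if (wavenumber[1] < wavenumber[length(wavenumber)]) {
    wavenumber <- rev(wavenumber)
    absorbance <- absorbance[, rev(seq_len(ncol(absorbance))), drop = FALSE]
  }
  metadata <- data.frame(spectrum_id = as.character(metadata$spectrum_id),
                         condition = as.character(metadata$condition),
                         stringsAsFactors = FALSE)
  rownames(absorbance) <- metadata$spectrum_id
  structure(
    list(wavenumber = as.numeric(wavenumber), absorbance = absorbance, metadata = metadata),
    class = "ftir_spectra_set"
  )
}

#' Extract one spectrum from a set
#'
#' @param set an `ftir_spectra_set`.
#' @param i row index or spectrum id.
#' @return An `ftir_spectrum`.
#' @export
get_spectrum <- function(set, i) {
  stopifnot(inherits(set, "ftir_spectra_set"))
  if (is.character(i)) i <- match(i, set$metadata$spectrum_id)
  if (is.na(i) || i < 1L || i > nrow(set$absorbance)) stop("spectrum not found", call. = FALSE)
  new_spectrum(set$wavenumber, set$absorbance[i, ],
               id = set$metadata$spectrum_id[i],
               condition = set$metadata$condition[i])
}

#' Combine spectra sets that share a grid
#'
#' @param ... `ftir_spectra_set` objects on identical grids.
#' @return A single `ftir_spectra_set`.
#' @export
bind_spectra_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  w <- sets[[1]]$wavenumber
  for (s in sets[-1]) {
    if (!isTRUE(all.equal(w, s$wavenumber, tolerance = 1e-12))) {
      stop("spectra sets are not on a common grid", call. = FALSE)
    }
  }
  new_spectra_set(
    w,
    do.call(rbind, lapply(sets, `[[`, "absorbance")),
    do.call(rbind, lapply(sets, `[[`, "metadata"))
  )
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %s (%s): %d points, %.1f-%.1f cm-1\n",
              x$id, x$condition, length(x$wavenumber),
              max(x$wavenumber), min(x$wavenumber)))
  invisible(x)
}

#' @export
print.ftir_spectra_set <- function(x, ...) {
  tab <- table(x$metadata$condition, useNA = "ifany")
  cat(sprintf("<ftir_spectra_set> %d spectra x %d points, %.1f-%.1f cm-1\n",
              nrow(x$absorbance), length(x$wavenumber),
              max(x$wavenumber), min(x$wavenumber)))
  cat("conditions:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}
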