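#' Read spectra from a wide CSV table
#'
#' Expects a header row, a first column of wavenumbers, and one column per
#' spectrum named by its id. An optional metadata CSV (`spectrum_id`,
#' `condition`) assigns condition labels; ids present in the metadata but
#' absent from the table are an error. The wavenumber column must be strictly
#' monotone and evenly spaced.
#'
#' @param table_path path to the wide CSV.
#' @param metadata_path optional path to the metadata CSV.
#' @return An `ftir_spectra_set`.
#' @export
read_spectra <- function(table_path, metadata_path = NULL) {
  tab <- utils::read.csv(table_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("spectra table needs a wavenumber column plus >= 1 spectrum", call. = FALSE)
  ok_num <- vapply(tab, is.numeric, logical(1))
  if (!all(ok_num)) {
    stop("non-numeric cells in columns: ", paste(names(tab)[!ok_num], collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(tab)) stop("missing values in spectra table (ragged rows?)", call. = FALSE)
  w <- tab[[1]]
  ids <- names(tab)[-1]
  if (anyDuplicated(ids)) stop("duplicate spectrum ids in header", call. = FALSE)
  mat <- t(as.matrix(tab[, -1, drop = FALSE]))
  meta <- data.frame(spectrum_id = ids, condition = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    meta_in <- read_metadata(metadata_path)
    unknown <- setdiff(meta_in$spectrum_id, ids)
    if (length(unknown)) {
      stop("metadata refers to unknown spectrum ids: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    meta$condition <- meta_in$condition[match(ids, meta_in$spectrum_id)]
  }
  new_spectra_set(w, mat, meta)
}

#' Read spectra from a long CSV table
#'
#' Alternative input layout with columns `spectrum_id`, `wavenumber`,
#' `absorbance`. All spectra must share the same grid.
#'
#' @inheritParams read_spectra
#' @return An `ftir_spectra_set`.
#' @export
read_spectra_long <- function(table_path, metadata_path = NULL) {
  tab <- utils::read.csv(table_path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "wavenumber", "absorbance")
  if (!all(need %in% names(tab))) {
    stop("long table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  ids <- unique(tab$spectrum_id)
  by_id <- split(tab[c("wavenumber", "absorbance")], factor(tab$spectrum_id, levels = ids))
  w <- by_id[[1]]$wavenumber
  mat <- matrix(NA_real_, nrow = length(ids), ncol = length(w))
  for (i in seq_along(ids)) {
    part <- by_id[[i]]
    if (nrow(part) != length(w) || !isTRUE(all.equal(part$wavenumber, w, tolerance = 1e-12))) {
      stop("spectrum ", ids[i], " is not on the shared wavenumber grid", call. = FALSE)
    }
    mat[i, ] <- part$absorbance
  }
  meta <- data.frame(spectrum_id = ids, condition = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    meta_in <- read_metadata(metadata_path)
    unknown <- setdiff(meta_in$spectrum_id, ids)
    if (length(unknown)) {
      stop("metadata refers to unknown spectrum ids: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    meta$condition <- meta_in$condition[match(ids, meta_in$spectrum_id)]
  }
  new_spectra_set(w, mat, meta)
}

read_metadata <- function(path) {
  meta <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (!all(c("spectrum_id", "condition") %in% names(meta))) {
    stop("metadata must have columns spectrum_id and condition", call. = FALSE)
  }
  if (anyDuplicated(meta$spectrum_id)) stop("duplicate spectrum ids in metadata", call. = FALSE)
  meta$condition[!is.na(meta$condition) & meta$condition == ""] <- NA_character_
  meta
}

#' Write spectra to wide CSV plus metadata CSV
#'
#' Writes the schema [read_spectra()] accepts, at full round-trip float
#' precision (shortest representation that re-reads to the identical double).
#' Missing condition labels are written as empty fields. Existing files are
#' overwritten.
#'
#' @param set an `ftir_spectra_set`.
#' @param table_path output path for the wide spectra CSV.
#' @param metadata_path output path for the metadata CSV (skipped if `NULL`).
#' @return Invisibly, `table_path`.
#' @export
write_spectra <- function(set, table_path, metadata_path = NULL) {
  stopifnot(inherits(set, "ftir_spectra_set"))
  tab <- data.frame(wavenumber = set$wavenumber, t(set$absorbance),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("wavenumber", set$metadata$spectrum_id)
  readr::write_csv(tab, table_path, progress = FALSE)
  if (!is.null(metadata_path)) {
    readr::write_csv(set$metadata, metadata_path, na = "", progress = FALSE)
  }
  invisible(table_path)
}

#' Write a result table as CSV
#'
#' Thin wrapper used by the pipeline for metrics, fit, and stats tables;
#' numeric fields are written at full precision, `NA` as empty.
#'
#' @param x data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_result_table <- function(x, path) {
  readr::write_csv(as.data.frame(x), path, na = "", progress = FALSE)
  invisible(path)
}
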