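#' Read spectra from a delimited text file
#'
#' The on-disk format is long-form delimited text with columns
#' `wavelength_nm`, `intensity`, `sample_id`, `fiber` (R1 or R2) and
#' `acquisition_index`; one record is one `(sample_id, fiber,
#' acquisition_index)` group. Wavelengths must be strictly increasing within
#' each record. Malformed input raises a format error naming the offending
#' row.
#'
#' @param path Path to a delimited text file (any separator `data.table`
#'   auto-detects).
#' @return A list of raw [spectrum_record()]s.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, showProgress = FALSE)
  if (nrow(dt) == 0) {
    warning("empty spectra file: ", path)
    return(list())
  }
  req <- c("wavelength_nm", "intensity", "sample_id", "fiber",
           "acquisition_index")
  miss <- setdiff(req, names(dt))
  if (length(miss))
    stop("spectra file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  # rows are reported as file lines (the header is line 1)
  bad_fiber <- which(!dt$fiber %in% c("R1", "R2"))
  if (length(bad_fiber))
    stop("unknown fiber label '", dt$fiber[bad_fiber[1]],
         "' at row ", bad_fiber[1] + 1L)
  if (anyNA(dt$wavelength_nm) || anyNA(dt$intensity))
    stop("missing wavelength or intensity at row ",
         which(is.na(dt$wavelength_nm) | is.na(dt$intensity))[1] + 1L)
  dt$..row <- seq_len(nrow(dt)) + 1L
  groups <- split(dt, by = c("sample_id", "fiber", "acquisition_index"),
                  sorted = TRUE)
  lapply(groups, function(g) {
    dw <- diff(g$wavelength_nm)
    if (length(dw) && any(dw <= 0)) {
      at <- g$..row[which(dw <= 0)[1] + 1L]
      stop("wavelengths not strictly increasing at row ", at,
           " (record ", g$sample_id[1], "/", g$fiber[1], "/",
           g$acquisition_index[1], ")")
    }
    spectrum_record(g$wavelength_nm, g$intensity, g$sample_id[1],
                    g$fiber[1], g$acquisition_index[1])
  })
}

#' Write spectra to a delimited text file
#'
#' Numeric columns are written with 17 significant digits so a
#' write-then-read round trip reproduces the values exactly.
#'
#' @param records List of non-concatenated [spectrum_record()]s.
#' @param path Output path (tab-separated).
#' @export
write_spectra <- function(records, path) {
  rows <- lapply(records, function(r) {
    if (is.null(r$wavelength))
      stop("concatenated records have no wavelength axis and cannot be ",
           "written in the long-form spectra format")
    data.table::data.table(
      wavelength_nm = sprintf("%.17g", r$wavelength),
      intensity = sprintf("%.17g", r$intensity),
      sample_id = r$sample_id,
      fiber = r$fiber,
      acquisition_index = r$acquisition_index
    )
  })
  data.table::fwrite(data.table::rbindlist(rows), path, sep = "\t",
                     quote = FALSE)
  invisible(path)
}

#' Read or write a cohort manifest
#'
#' The manifest is one row per tissue sample: `sample_id`, `age_months`,
#' `region`, `true_nd`, `profile_group`, `nd_class`.
#'
#' @param cohort Data frame as returned by [generate_cohort()].
#' @param path File path (tab-separated text).
#' @return `read_cohort()` returns the manifest data frame.
#' @export
write_cohort <- function(cohort, path) {
  data.table::fwrite(cohort, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  as.data.frame(data.table::fread(path, showProgress = FALSE))
}
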