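#' Spectrum records
#'
#' A `spectrum_record` holds one acquisition's intensity trace from one
#' collection fiber (R1 or R2) on a strictly increasing wavelength grid,
#' together with the metadata needed to pair and pool acquisitions:
#' `sample_id`, `fiber` and `acquisition_index`. Preprocessing functions
#' ([normalize_to_mean()], [gaussian_smooth()], [window_wavelengths()],
#' [concatenate_fibers()], [downsample_by_factor()]) stamp state flags on the
#' record and refuse out-of-order application, so a record always documents
#' how far along the fixed chain
#' normalize -> filter -> (window) -> concatenate -> (downsample) it is.
#'
#' After [concatenate_fibers()] the natural axis is an index axis rather than
#' a wavelength axis; `wavelength` is then `NULL` and `fiber` is `"R1+R2"`.
#'
#' @param wavelength Strictly increasing numeric vector of wavelengths (nm),
#'   or `NULL` for concatenated records.
#' @param intensity Numeric vector of intensities (a.u.), same length as the
#'   grid.
#' @param sample_id Character scalar identifying the tissue sample.
#' @param fiber `"R1"` or `"R2"` (or `"R1+R2"` once concatenated).
#' @param acquisition_index Positive integer; which of the sample's probe
#'   placements this trace came from.
#' @param state Character vector of preprocessing flags, a subset of
#'   `c("normalized", "filtered", "windowed", "concatenated", "downsampled")`.
#' @return An object of class `spectrum_record`.
#' @export
spectrum_record <- function(wavelength, intensity, sample_id, fiber,
                            acquisition_index, state = character()) {
  rec <- structure(
    list(
      wavelength = wavelength,
      intensity = as.numeric(intensity),
      sample_id = as.character(sample_id),
      fiber = as.character(fiber),
      acquisition_index = as.integer(acquisition_index),
      state = state
    ),
    class = "spectrum_record"
  )
  validate_spectrum_record(rec)
  rec
}

VALID_STATES <- c("normalized", "filtered", "windowed", "concatenated",
                  "downsampled")

validate_spectrum_record <- function(rec) {
  if (!is.null(rec$wavelength)) {
    if (length(rec$wavelength) != length(rec$intensity))
      stop("intensity length (", length(rec$intensity),
           ") does not match wavelength grid length (",
           length(rec$wavelength), ")")
    if (length(rec$wavelength) > 1 && any(diff(rec$wavelength) <= 0))
      stop("wavelength grid must be strictly increasing")
  }
  if (!rec$fiber %in% c("R1", "R2", "R1+R2"))
    stop("unknown fiber label '", rec$fiber, "' (expected R1, R2 or R1+R2)")
  if (!all(rec$state %in% VALID_STATES))
    stop("unknown preprocessing state flag(s): ",
         paste(setdiff(rec$state, VALID_STATES), collapse = ", "))
  if ("normalized" %in% rec$state &&
      abs(mean(rec$intensity) - 1) > 1e-9)
    stop("record flagged normalized but mean intensity is ",
         format(mean(rec$intensity)))
  invisible(rec)
}

has_state <- function(rec, flag) flag %in% rec$state

require_state <- function(rec, flag, op) {
  if (!has_state(rec, flag))
    stop(op, " requires a ", flag,
         " record; preprocessing order is normalize -> filter -> (window) ",
         "-> concatenate -> (downsample)")
}

forbid_state <- function(rec, flag, op) {
  if (has_state(rec, flag))
    stop(op, " cannot be applied to an already ", flag, " record; ",
         "preprocessing order is normalize -> filter -> (window) ",
         "-> concatenate -> (downsample)")
}

#' @export
print.spectrum_record <- function(x, ...) {
  n <- length(x$intensity)
  ax <- if (is.null(x$wavelength)) "index axis"
        else sprintf("%.1f-%.1f nm", min(x$wavelength), max(x$wavelength))
  st <- if (length(x$state)) paste(x$state, collapse = ",") else "raw"
  cat(sprintf("<spectrum_record> %s %s acq %d | %d pts (%s) | %s\n",
              x$sample_id, x$fiber, x$acquisition_index, n, ax, st))
  invisible(x)
}

#' Stack spectrum records into a matrix
#'
#' Pools a list of equal-length records into one matrix (one row per record)
#' plus a metadata data frame, the layout the clustering and CNN stages
#' consume.
#'
#' @param records List of [spectrum_record()] objects of equal length.
#' @return A list with `x` (numeric matrix, records in rows) and `meta`
#'   (data frame with `sample_id`, `fiber`, `acquisition_index`).
#' @export
spectra_to_matrix <- function(records) {
  stopifnot(length(records) >= 1)
  lens <- vapply(records, function(r) length(r$intensity), integer(1))
  if (length(unique(lens)) != 1)
    stop("records have unequal lengths (",
         paste(unique(lens), collapse = ", "),
         "); window/downsample them identically first")
  x <- do.call(rbind, lapply(records, function(r) r$intensity))
  meta <- data.frame(
    sample_id = vapply(records, function(r) r$sample_id, character(1)),
    fiber = vapply(records, function(r) r$fiber, character(1)),
    acquisition_index = vapply(records, function(r) r$acquisition_index,
                               integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(x) <- paste(meta$sample_id, meta$fiber, meta$acquisition_index,
                       sep = "_")
  list(x = x, meta = meta)
}
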