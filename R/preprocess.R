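#' Normalize a spectrum to its mean intensity
#'
#' Divides the trace by its mean so the result has mean exactly 1. This
#' removes acquisition-to-acquisition gain differences (integration geometry,
#' probe contact) while preserving spectral shape; it is the first step of
#' the fixed preprocessing chain and is idempotent.
#'
#' @param record A raw [spectrum_record()].
#' @return The record with unit mean intensity and the `normalized` flag set.
#' @export
normalize_to_mean <- function(record) {
  forbid_state(record, "filtered", "normalize_to_mean")
  forbid_state(record, "concatenated", "normalize_to_mean")
  m <- mean(record$intensity)
  if (!is.finite(m) || m <= 0)
    stop("cannot normalize: mean intensity is ", format(m))
  record$intensity <- record$intensity / m
  record$state <- union(record$state, "normalized")
  record
}

#' Gaussian filter specification
#'
#' The smoothing filter is specified in measures (grid samples), not
#' nanometres: a standard deviation of 20 measures and a kernel size of 80
#' measures, i.e. a symmetric truncated Gaussian supported on +/- 40 samples
#' and renormalized to unit sum (DC gain exactly 1).
#'
#' @param sd_measures Kernel standard deviation in samples (default 20,
#'   roughly 3.3 nm on the default 3648-point grid).
#' @param kernel_measures Kernel size in samples (default 80; the kernel is
#'   truncated at +/- `kernel_measures / 2`).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(sd_measures = 20, kernel_measures = 80) {
  stopifnot(sd_measures > 0, kernel_measures >= 1)
  structure(list(sd_measures = sd_measures,
                 kernel_measures = as.integer(kernel_measures)),
            class = "filter_spec")
}

#' Gaussian kernel used by the smoother
#' @keywords internal
gaussian_kernel <- function(sd, size) {
  half <- floor(size / 2)
  k <- exp(-(seq(-half, half))^2 / (2 * sd^2))
  k / sum(k)
}

#' One-dimensional Gaussian filtering of a numeric trace
#'
#' Direct convolution with a truncated, renormalized Gaussian kernel.
#' Boundaries are handled by mirror reflection about the edge sample (the
#' edge value itself is not duplicated), which avoids edge droop on
#' normalized traces.
#'
#' @param x Numeric vector.
#' @param sd_measures,kernel_measures As in [filter_spec()].
#' @return Filtered numeric vector, same length as `x`.
#' @export
gaussian_filter1d <- function(x, sd_measures = 20, kernel_measures = 80) {
  n <- length(x)
  half <- floor(kernel_measures / 2)
  if (n < kernel_measures)
    stop("trace length (", n, ") is shorter than the kernel size (",
         kernel_measures, ")")
  k <- gaussian_kernel(sd_measures, kernel_measures)
  # mirror padding: x[half+1], ..., x[2] | x | x[n-1], ..., x[n-half]
  xp <- c(x[(half + 1):2], x, x[(n - 1):(n - half)])
  out <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(out[(half + 1):(half + n)])
}

#' Smooth a spectrum with the configured Gaussian filter
#'
#' @param record A normalized [spectrum_record()].
#' @param spec A [filter_spec()].
#' @return The record with smoothed intensities and the `filtered` flag set.
#' @export
gaussian_smooth <- function(record, spec = filter_spec()) {
  require_state(record, "normalized", "gaussian_smooth")
  forbid_state(record, "concatenated", "gaussian_smooth")
  forbid_state(record, "filtered", "gaussian_smooth")
  record$intensity <- gaussian_filter1d(record$intensity,
                                        spec$sd_measures,
                                        spec$kernel_measures)
  record$state <- union(record$state, "filtered")
  record
}

#' Restrict a spectrum to a wavelength window
#'
#' Keeps grid points with `lo_nm <= lambda < hi_nm`. The half-open
#' convention makes consecutive windows partition the grid; as the one
#' exception, a window whose upper edge reaches the grid maximum is treated
#' as closed, so windowing over the full native range is the identity and the
#' three 200-nm analysis windows jointly cover every point exactly once.
#' Windowing applies per fiber, before concatenation.
#'
#' @param record A filtered, non-concatenated [spectrum_record()].
#' @param lo_nm,hi_nm Window edges in nm, `lo_nm < hi_nm`.
#' @return The windowed record with the `windowed` flag set.
#' @export
window_wavelengths <- function(record, lo_nm, hi_nm) {
  forbid_state(record, "concatenated", "window_wavelengths")
  require_state(record, "filtered", "window_wavelengths")
  stopifnot(lo_nm < hi_nm)
  wl <- record$wavelength
  keep <- wl >= lo_nm & (wl < hi_nm | (hi_nm >= max(wl) & wl <= hi_nm))
  if (!any(keep))
    stop("window [", lo_nm, ", ", hi_nm, ") contains no grid points")
  record$wavelength <- wl[keep]
  record$intensity <- record$intensity[keep]
  record$state <- union(record$state, "windowed")
  record
}

#' Concatenate the two collection-fiber traces of one acquisition
#'
#' Joins the R1 and R2 traces of the same acquisition end to end (R1 first),
#' producing the single feature vector used by clustering and the CNN. The
#' axis of the result is an index axis; both inputs must already be
#' normalized and filtered (and, if windowed, windowed identically).
#'
#' @param r1,r2 Normalized, filtered [spectrum_record()]s from fibers R1 and
#'   R2 of the same `sample_id` and `acquisition_index`.
#' @return A concatenated record (`fiber = "R1+R2"`, `wavelength = NULL`).
#' @export
concatenate_fibers <- function(r1, r2) {
  for (r in list(r1, r2)) {
    require_state(r, "normalized", "concatenate_fibers")
    require_state(r, "filtered", "concatenate_fibers")
    forbid_state(r, "concatenated", "concatenate_fibers")
  }
  if (r1$fiber != "R1" || r2$fiber != "R2")
    stop("concatenate_fibers expects fibers (R1, R2), got (",
         r1$fiber, ", ", r2$fiber, ")")
  if (r1$sample_id != r2$sample_id ||
      r1$acquisition_index != r2$acquisition_index)
    stop("pairing error: (", r1$sample_id, ", acq ", r1$acquisition_index,
         ") vs (", r2$sample_id, ", acq ", r2$acquisition_index, ")")
  out <- structure(
    list(
      wavelength = NULL,
      intensity = c(r1$intensity, r2$intensity),
      sample_id = r1$sample_id,
      fiber = "R1+R2",
      acquisition_index = r1$acquisition_index,
      state = union(intersect(r1$state, r2$state), "concatenated")
    ),
    class = "spectrum_record"
  )
  attr(out, "n_r1") <- length(r1$intensity)
  attr(out, "n_r2") <- length(r2$intensity)
  out
}

#' Resolution-reduction specification
#'
#' @param K Scale factor (real, `K >= 1`). A trace of length `N` is reduced
#'   to `M = max(2, round(N / K))` samples.
#' @return A `downsample_spec` list.
#' @export
downsample_spec <- function(K) {
  if (!is.numeric(K) || length(K) != 1 || K < 1)
    stop("downsample scale K must be a single number >= 1")
  structure(list(K = as.numeric(K)), class = "downsample_spec")
}

#' Reduce the resolution of a numeric trace by a factor K
#'
#' Evaluates the trace by linear interpolation at `M = max(2, round(N / K))`
#' evenly spaced fractional positions over `[0, N - 1]`. `K = 1` is the
#' identity and any affine (linear-ramp) signal is reproduced exactly for
#' every `K`; non-integer `K` from a logarithmic scale schedule is supported.
#'
#' @param x Numeric vector of length at least 2.
#' @param K Scale factor, `K >= 1`.
#' @return Numeric vector of length `M`.
#' @export
downsample1d <- function(x, K) {
  spec <- downsample_spec(K)
  n <- length(x)
  if (n < 2) stop("trace must have at least 2 samples")
  m <- max(2L, as.integer(round(n / spec$K)))
  pos <- seq(0, n - 1, length.out = m)
  stats::approx(x = seq_len(n) - 1, y = x, xout = pos)$y
}

#' Downsample a concatenated spectrum by a factor K
#'
#' @param record A concatenated [spectrum_record()].
#' @param spec A [downsample_spec()].
#' @return The record at reduced resolution with the `downsampled` flag set.
#' @export
downsample_by_factor <- function(record, spec) {
  require_state(record, "concatenated", "downsample_by_factor")
  record$intensity <- downsample1d(record$intensity, spec$K)
  record$state <- union(record$state, "downsampled")
  record
}

#' Run the fixed preprocessing chain over raw fiber records
#'
#' Applies normalize -> filter -> (window) -> concatenate to a list of raw
#' per-fiber records, pairing R1 with R2 by `(sample_id, acquisition_index)`.
#'
#' @param records List of raw [spectrum_record()]s containing an R1 and an R2
#'   trace for every acquisition.
#' @param spec A [filter_spec()].
#' @param window Optional `c(lo_nm, hi_nm)` window applied per fiber before
#'   concatenation.
#' @return List of concatenated records, ordered by sample then acquisition.
#' @export
preprocess_spectra <- function(records, spec = filter_spec(), window = NULL) {
  records <- lapply(records, function(r) {
    r <- gaussian_smooth(normalize_to_mean(r), spec)
    if (!is.null(window)) r <- window_wavelengths(r, window[1], window[2])
    r
  })
  key <- vapply(records, function(r)
    paste(r$sample_id, r$acquisition_index, sep = "\r"), character(1))
  out <- lapply(split(records, key), function(pair) {
    fib <- vapply(pair, function(r) r$fiber, character(1))
    if (length(pair) != 2 || !setequal(fib, c("R1", "R2")))
      stop("acquisition ", pair[[1]]$sample_id, "/",
           pair[[1]]$acquisition_index,
           " does not have exactly one R1 and one R2 trace")
    concatenate_fibers(pair[[which(fib == "R1")]], pair[[which(fib == "R2")]])
  })
  ord <- order(vapply(out, function(r) r$sample_id, character(1)),
               vapply(out, function(r) r$acquisition_index, integer(1)))
  unname(out[ord])
}
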