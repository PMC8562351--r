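test_that("mean normalization rescales, preserves shape and is idempotent", {
  rec <- make_raw_record(c(1, 2, 3), wavelength = c(500, 600, 700))
  nrm <- normalize_to_mean(rec)
  expect_equal(nrm$intensity, c(0.5, 1, 1.5))
  expect_true("normalized" %in% nrm$state)

  const <- normalize_to_mean(make_raw_record(rep(5, 100)))
  expect_equal(const$intensity, rep(1, 100))

  rec2 <- make_raw_record(runif(200, 1, 3))
  once <- normalize_to_mean(rec2)
  expect_equal(normalize_to_mean(once)$intensity, once$intensity)

  expect_error(normalize_to_mean(make_raw_record(rep(0, 50))), "normalize")
})

test_that("Gaussian smoothing matches a direct-summation impulse oracle", {
  n <- 201
  x <- numeric(n); x[101] <- 1
  out <- gaussian_filter1d(x, sd_measures = 20, kernel_measures = 80)
  # oracle: truncated renormalized Gaussian, taps at -40..40
  taps <- -40:40
  kern <- exp(-taps^2 / (2 * 20^2)); kern <- kern / sum(kern)
  expect_equal(out[101 + taps], kern, tolerance = 1e-12)
})

test_that("the smoother is linear with unit DC gain and mean-preserving", {
  set.seed(3)
  a <- runif(400); b <- runif(400)
  sab <- gaussian_filter1d(a + b)
  expect_equal(sab, gaussian_filter1d(a) + gaussian_filter1d(b),
               tolerance = 1e-9)
  expect_equal(gaussian_filter1d(rep(2.5, 300)), rep(2.5, 300))
  # mean preservation on a normalized trace
  rec <- norm_filt(make_raw_record(runif(500, 1, 2)))
  expect_equal(mean(rec$intensity), 1, tolerance = 1e-3)
  expect_error(gaussian_filter1d(runif(50), 20, 80), "shorter than the kernel")
})

test_that("wavelength windows follow the half-open partition convention", {
  rec <- norm_filt(make_raw_record(runif(3648, 1, 2)))
  full <- window_wavelengths(rec, 500, 1100)
  expect_equal(full$intensity, rec$intensity)  # full range is the identity

  w1 <- window_wavelengths(rec, 500, 700)
  w2 <- window_wavelengths(rec, 700, 900)
  w3 <- window_wavelengths(rec, 900, 1100)
  expect_equal(length(w2$intensity), 1216)
  expect_equal(length(w1$intensity) + length(w2$intensity) +
                 length(w3$intensity), 3648)
  expect_length(intersect(w1$wavelength, w2$wavelength), 0)
  expect_error(window_wavelengths(rec, 2000, 2100), "no grid points")
})

test_that("fiber concatenation pairs metadata and stacks R1 before R2", {
  r1 <- norm_filt(make_raw_record(runif(3648, 1, 2), fiber = "R1"))
  r2 <- norm_filt(make_raw_record(runif(3648, 1, 2), fiber = "R2"))
  cc <- concatenate_fibers(r1, r2)
  expect_length(cc$intensity, 7296)
  expect_equal(cc$intensity[1:3648], r1$intensity)
  expect_equal(cc$intensity[3649:7296], r2$intensity)
  expect_identical(cc$fiber, "R1+R2")

  # self-concatenation symmetry through a relabeled copy
  r1b <- r1; r1b$fiber <- "R2"
  sym <- concatenate_fibers(r1, r1b)
  expect_equal(sym$intensity[1:3648], sym$intensity[3649:7296])

  r2bad <- norm_filt(make_raw_record(runif(3648), fiber = "R2", acq = 2L))
  expect_error(concatenate_fibers(r1, r2bad), "pairing error")
  expect_error(concatenate_fibers(r2, r1), "expects fibers")
})

test_that("preprocessing refuses out-of-order application", {
  raw <- make_raw_record(runif(3648, 1, 2))
  expect_error(gaussian_smooth(raw), "normalized")
  expect_error(window_wavelengths(normalize_to_mean(raw), 500, 700),
               "filtered")
  nf <- norm_filt(raw)
  expect_error(normalize_to_mean(nf), "filtered")
  expect_error(downsample_by_factor(nf, downsample_spec(10)), "concatenated")
})

test_that("downsampling follows the round(N/K) linear-interpolation rule", {
  x <- runif(7296)
  expect_length(downsample1d(x, 50), 146)
  expect_equal(downsample1d(x, 1), x)  # K = 1 positions land on integers
  # exact on affine signals for arbitrary (non-integer) K
  ramp <- seq(-3, 8, length.out = 1000)
  for (K in c(2, 7.3, 50, 333.3)) {
    out <- downsample1d(ramp, K)
    expect_equal(out, seq(-3, 8, length.out = length(out)), tolerance = 1e-9)
  }
  expect_error(downsample_spec(0.5), "K must be")
})

test_that("spectra survive a write-read round trip exactly", {
  set.seed(11)
  cohort <- generate_cohort(cohort_config(seed = 2))
  recs <- generate_sample_spectra(cohort[1, ],
                                  spectrum_gen_config(n_points_per_fiber = 64),
                                  n_acquisitions = 3, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectra(recs, path)
  back <- read_spectra(path)
  expect_length(back, length(recs))
  key <- function(r) paste(r$sample_id, r$fiber, r$acquisition_index)
  back <- back[match(vapply(recs, key, ""), vapply(back, key, ""))]
  for (i in seq_along(recs)) {
    expect_identical(back[[i]]$intensity, recs[[i]]$intensity)
    expect_identical(back[[i]]$wavelength, recs[[i]]$wavelength)
  }
})

test_that("malformed spectra files raise format errors naming the row", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("wavelength_nm\tintensity\tsample_id\tfiber\tacquisition_index",
               "500\t1.0\tS01\tR1\t1",
               "499\t1.1\tS01\tR1\t1"), path)
  expect_error(read_spectra(path), "strictly increasing at row 3")

  writeLines(c("wavelength_nm\tintensity\tsample_id\tfiber\tacquisition_index",
               "500\t1.0\tS01\tR9\t1"), path)
  expect_error(read_spectra(path), "unknown fiber label")

  writeLines("wavelength_nm\tintensity\tsample_id\tfiber\tacquisition_index",
             path)
  expect_warning(empty <- read_spectra(path), "empty")
  expect_length(empty, 0)
})
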