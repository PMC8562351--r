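# Shared fixtures. The default 440-spectrum dataset is expensive to build,
# so it is generated once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

default_dataset <- function(seed = 1) {
  key <- paste0("ds", seed)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- simulate_spectrum_dataset(seed = seed)
  .fixture_env[[key]]
}

# nine-sample cohort with three samples per ND class, so removing the test
# and validation samples always leaves every class in training; small and
# separable, used by the LOOCV tests
tiny_cohort_config <- function(n_acquisitions = 4, seed = 7) {
  cohort_config(n_samples = 9,
                ages_months = c(4.3, 4.35, 4.4, 6.6, 6.7, 6.8, 30, 40, 50),
                n_acquisitions_per_sample = n_acquisitions,
                n_profile_groups = 3,
                seed = seed)
}

tiny_dataset <- function(n_acquisitions = 4, seed = 7, gen = spectrum_gen_config()) {
  ds <- simulate_spectrum_dataset(tiny_cohort_config(n_acquisitions, seed),
                                  gen = gen, seed = seed)
  list(x = ds$x, sample_id = ds$meta$sample_id, class = ds$meta$nd_class,
       cohort = ds$cohort)
}

# independent layer-shape / parameter-count oracle for the Table-style stack:
# written directly from the stride/kernel arithmetic, not via the package
oracle_network_params <- function(input_length, padding = "valid") {
  conv <- function(L) if (padding == "same") ceiling(L / 2)
                      else floor((L - 5) / 2) + 1
  L <- conv(input_length)          # conv1, 1 -> 3 channels
  L <- conv(L)                     # conv2
  L <- floor(L / 2)                # pool1
  L <- conv(L)                     # conv3
  L <- floor(L / 2)                # pool2
  if (L < 1) stop("infeasible")
  nflat <- 3 * L
  (5 * 1 * 3 + 3) + (5 * 3 * 3 + 3) + (5 * 3 * 3 + 3) +
    (nflat * 3 + 3)
}

# raw record helpers
make_raw_record <- function(intensity, wavelength = NULL, sample_id = "S01",
                            fiber = "R1", acq = 1L) {
  if (is.null(wavelength))
    wavelength <- seq(500, 1100, length.out = length(intensity))
  spectrum_record(wavelength, intensity, sample_id, fiber, acq)
}

norm_filt <- function(rec, spec = filter_spec()) {
  gaussian_smooth(normalize_to_mean(rec), spec)
}
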