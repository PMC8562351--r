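#' Synthetic cohort configuration
#'
#' Describes the simulated study: 22 ventricular tissue samples spanning
#' gestational ages 4.3 to 56 months, 20 fiber-pair spectrum acquisitions per
#' sample, and five spectral profile groups planted along the nuclear-density
#' axis.
#'
#' The default ages form five tight age clumps (5/4/5/4/4 samples). Under the
#' default [nd_age_model()] the clumps map to five well-separated ND levels,
#' none of which straddles a class boundary of the low/medium/high scheme
#' (2000 and 3800 nuclei/mm^2), so the profile groups assigned by ND quantile
#' coincide with the clumps and every ND class holds at least five samples.
#'
#' @param n_samples Number of tissue samples (default 22).
#' @param ages_months Ages in months, one per sample.
#' @param n_acquisitions_per_sample Spectra gathered per sample (default 20).
#' @param n_profile_groups Planted spectral groups (default 5).
#' @param nd_scatter_sd Lognormal SD of per-sample ND about the age model
#'   (default 0.03).
#' @param seed Integer seed for cohort generation.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 22,
                          ages_months = c(4.3, 4.3, 4.35, 4.4, 4.45,
                                          5.0, 5.1, 5.2, 5.3,
                                          6.6, 6.65, 6.7, 6.75, 6.8,
                                          9.3, 9.5, 9.7, 9.9,
                                          26, 34, 45, 56),
                          n_acquisitions_per_sample = 20,
                          n_profile_groups = 5,
                          nd_scatter_sd = 0.03,
                          seed = 1L) {
  ages_months <- as.numeric(unlist(ages_months))
  if (n_samples < 3) stop("n_samples must be >= 3")
  if (length(ages_months) != n_samples)
    stop("ages_months must have one age per sample")
  if (any(ages_months <= 0)) stop("all ages must be positive")
  if (n_profile_groups > n_samples)
    stop("n_profile_groups must not exceed n_samples")
  structure(list(n_samples = as.integer(n_samples),
                 ages_months = ages_months,
                 n_acquisitions_per_sample =
                   as.integer(n_acquisitions_per_sample),
                 n_profile_groups = as.integer(n_profile_groups),
                 nd_scatter_sd = nd_scatter_sd,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate synthetic sample metadata for a study cohort
#'
#' Draws one metadata record per tissue sample: a true nuclear density from
#' the ND-age model with small lognormal sample scatter, an anatomical
#' region (RV for all but the two extra samples of the youngest age, which
#' come from the LV and septum), the ND class label, and a profile group
#' assigned by ND quantile.
#'
#' @param config A [cohort_config()].
#' @param nd_model An [nd_age_model()].
#' @return Data frame with columns `sample_id`, `age_months`, `region`,
#'   `true_nd`, `nd_class`, `profile_group`.
#' @export
generate_cohort <- function(config = cohort_config(),
                            nd_model = nd_age_model()) {
  set.seed(config$seed)
  n <- config$n_samples
  age <- config$ages_months
  true_nd <- nd_from_age(nd_model, age) *
    exp(stats::rnorm(n, 0, config$nd_scatter_sd))
  region <- rep("RV", n)
  young <- order(age)[seq_len(min(3, n))]
  if (n > length(unique(age))) {
    region[young[2]] <- "LV"
    region[young[3]] <- "septum"
  }
  # profile groups: equal-count ND quantile bins, group 1 = lowest ND
  grp <- as.integer(cut(rank(true_nd, ties.method = "first"),
                        breaks = config$n_profile_groups, labels = FALSE))
  data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    age_months = age,
    region = region,
    true_nd = true_nd,
    nd_class = assign_nd_class(true_nd),
    profile_group = grp,
    stringsAsFactors = FALSE
  )
}

#' Spectrum generator configuration
#'
#' Phenomenological model of one acquisition's fiber-pair spectra:
#' `I(lambda) = B_f(lambda) * [1 + s * g * ramp(lambda) +
#' o * g * sin(2 pi lambda / P_f + phi_sample)] * gain * (1 + noise)`,
#' where `B_f` is a fiber-specific skewed broadband baseline, `ramp` spans
#' -1/2..1/2 over the grid, `g` is a centered, scaled (log) ND score of the
#' sample, `gain` is a per-acquisition multiplicative log-normal gain and
#' `noise` is smoothed additive noise. Mean normalization removes `gain`
#' exactly; the slope and oscillation terms carry the ND signal and dominate
#' the between-sample variance, giving the low-rank structure and the
#' within-sample R^2 >= 0.999 the downstream analyses assume.
#'
#' @param wavelength_min_nm,wavelength_max_nm Grid range (defaults 500, 1100).
#' @param n_points_per_fiber Grid length per fiber (default 3648).
#' @param baseline List of per-fiber baseline parameters (`peak_nm`,
#'   `width_nm`, `skew`, `offset`).
#' @param slope_coupling ND-to-spectral-tilt strength (default 0.08).
#' @param oscillation_coupling ND-to-oscillation strength (default 0.05).
#' @param oscillation_period_nm Per-fiber oscillation periods (defaults
#'   R1 150 nm, R2 110 nm).
#' @param phase_sd Per-sample oscillation phase SD in radians (default 0.05);
#'   this is what makes between-sample differences subtle but nonzero within
#'   a profile group.
#' @param gain_sd Per-acquisition multiplicative log-gain SD (default 0.05).
#' @param noise_sd Additive relative noise SD (default 0.005).
#' @param noise_smooth_sd Gaussian SD (samples) of the noise smoothing
#'   (default 5), emulating detector correlation.
#' @param nd_log_center,nd_log_scale Centering and scale of the log-ND score
#'   `g = (log(ND) - nd_log_center) / nd_log_scale` (defaults log(2800) and
#'   0.76, placing the default cohort's g in about -1..1).
#' @param signal_band_nm Optional `c(lo, hi)` band outside which the ND
#'   couplings are switched off (used to study wavelength localization);
#'   default `NULL` (whole range).
#' @return A `spectrum_gen_config` list.
#' @export
spectrum_gen_config <- function(wavelength_min_nm = 500,
                                wavelength_max_nm = 1100,
                                n_points_per_fiber = 3648,
                                baseline = list(
                                  R1 = list(peak_nm = 630, width_nm = 120,
                                            skew = 3, offset = 0.15),
                                  R2 = list(peak_nm = 760, width_nm = 160,
                                            skew = 2, offset = 0.20)),
                                slope_coupling = 0.08,
                                oscillation_coupling = 0.05,
                                oscillation_period_nm = c(R1 = 150, R2 = 110),
                                phase_sd = 0.05,
                                gain_sd = 0.05,
                                noise_sd = 0.005,
                                noise_smooth_sd = 5,
                                nd_log_center = log(2800),
                                nd_log_scale = 0.76,
                                signal_band_nm = NULL) {
  stopifnot(wavelength_min_nm < wavelength_max_nm, n_points_per_fiber >= 2)
  cfg <- structure(as.list(environment()), class = "spectrum_gen_config")
  # worst-case modulation must keep intensities positive for |g| <= 1.5
  worst <- 1.5 * (slope_coupling / 2 + oscillation_coupling)
  if (worst >= 1)
    stop("couplings produce non-positive intensities (worst-case ",
         "modulation ", signif(worst, 3), " >= 1)")
  cfg
}

#' Evaluate the fiber baseline shape
#' @keywords internal
fiber_baseline <- function(wl, bp) {
  u <- (wl - bp$peak_nm) / bp$width_nm
  b <- 2 * stats::dnorm(u) * stats::pnorm(bp$skew * u)
  bp$offset + b / max(b)
}

#' Centered, scaled log-ND score of a sample
#' @keywords internal
nd_score <- function(true_nd, gen) {
  (log(true_nd) - gen$nd_log_center) / gen$nd_log_scale
}

#' Generate the fiber-pair spectra of one sample
#'
#' Produces `n_acquisitions` raw (R1, R2) record pairs for one sample under
#' the model described in [spectrum_gen_config()]. Deterministic given
#' `seed`; with `noise_sd = 0` and `gain_sd = 0` all acquisitions of the
#' sample are identical.
#'
#' @param meta One-row data frame (or list) with `sample_id` and `true_nd`.
#' @param gen A [spectrum_gen_config()].
#' @param n_acquisitions Number of probe placements (default 20).
#' @param seed Integer seed.
#' @return A list of length `2 * n_acquisitions` of raw [spectrum_record()]s
#'   (R1 and R2 of acquisition 1, then acquisition 2, ...).
#' @export
generate_sample_spectra <- function(meta, gen = spectrum_gen_config(),
                                    n_acquisitions = 20, seed = 1L) {
  set.seed(seed)
  wl <- seq(gen$wavelength_min_nm, gen$wavelength_max_nm,
            length.out = gen$n_points_per_fiber)
  g <- nd_score(meta$true_nd, gen)
  phi <- stats::rnorm(1, 0, gen$phase_sd)
  band <- if (is.null(gen$signal_band_nm)) rep(1, length(wl))
          else as.numeric(wl >= gen$signal_band_nm[1] &
                          wl <= gen$signal_band_nm[2])
  ramp <- (wl - mean(wl)) / diff(range(wl))
  out <- vector("list", 2L * n_acquisitions)
  for (acq in seq_len(n_acquisitions)) {
    gain <- exp(stats::rnorm(1, 0, gen$gain_sd))
    for (f in c("R1", "R2")) {
      base <- fiber_baseline(wl, gen$baseline[[f]])
      osc <- sin(2 * pi * wl / gen$oscillation_period_nm[[f]] + phi)
      signal <- 1 + band * g * (gen$slope_coupling * ramp +
                                gen$oscillation_coupling * osc)
      eps <- stats::rnorm(length(wl), 0, 1)
      if (gen$noise_sd > 0 && gen$noise_smooth_sd > 0) {
        eps <- gaussian_filter1d(eps, gen$noise_smooth_sd,
                                 ceiling(4 * gen$noise_smooth_sd))
        eps <- eps / stats::sd(eps)
      }
      intens <- base * signal * gain * (1 + gen$noise_sd * eps)
      if (any(intens <= 0))
        stop("configuration produced non-positive intensities")
      idx <- 2L * (acq - 1L) + if (f == "R1") 1L else 2L
      out[[idx]] <- spectrum_record(wl, intens, meta$sample_id, f, acq)
    }
  }
  out
}

#' Generate all raw spectra of a cohort
#'
#' Calls [generate_sample_spectra()] for every sample with per-sample seeds
#' derived from the master seed; deterministic given the seed.
#'
#' @param cohort Data frame from [generate_cohort()].
#' @param gen A [spectrum_gen_config()].
#' @param n_acquisitions Acquisitions per sample (default 20).
#' @param seed Master integer seed.
#' @return A list of raw [spectrum_record()]s (two per acquisition).
#' @export
generate_cohort_spectra <- function(cohort, gen = spectrum_gen_config(),
                                    n_acquisitions = 20, seed = 1L) {
  set.seed(seed)
  sample_seeds <- sample.int(.Machine$integer.max - 1L, nrow(cohort))
  do.call(c, lapply(seq_len(nrow(cohort)), function(i) {
    generate_sample_spectra(cohort[i, ], gen, n_acquisitions,
                            sample_seeds[i])
  }))
}

#' Generate, preprocess and stack the default synthetic spectrum set
#'
#' Convenience wrapper producing the full analysis-ready dataset: cohort
#' metadata, the 440 concatenated normalized filtered spectra as a matrix,
#' and per-spectrum metadata joined with sample truth.
#'
#' @param config A [cohort_config()].
#' @param nd_model An [nd_age_model()].
#' @param gen A [spectrum_gen_config()].
#' @param spec A [filter_spec()].
#' @param window Optional wavelength window `c(lo, hi)` applied per fiber.
#' @param seed Master seed (defaults to `config$seed`).
#' @return A list with `cohort` (sample metadata), `x` (spectra matrix),
#'   `meta` (per-spectrum metadata with `sample_id`, `acquisition_index`,
#'   `true_nd`, `nd_class`, `profile_group`).
#' @export
simulate_spectrum_dataset <- function(config = cohort_config(),
                                      nd_model = nd_age_model(),
                                      gen = spectrum_gen_config(),
                                      spec = filter_spec(),
                                      window = NULL,
                                      seed = config$seed) {
  cohort <- generate_cohort(config, nd_model)
  raw <- generate_cohort_spectra(cohort, gen,
                                 config$n_acquisitions_per_sample, seed)
  conc <- preprocess_spectra(raw, spec, window)
  sm <- spectra_to_matrix(conc)
  idx <- match(sm$meta$sample_id, cohort$sample_id)
  sm$meta$true_nd <- cohort$true_nd[idx]
  sm$meta$nd_class <- cohort$nd_class[idx]
  sm$meta$profile_group <- cohort$profile_group[idx]
  list(cohort = cohort, x = sm$x, meta = sm$meta)
}
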