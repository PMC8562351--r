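test_that("mode-plus-2SD thresholding isolates bright nuclei", {
  set.seed(21)
  img <- matrix(rnorm(100 * 100, mean = 100, sd = 5), 100, 100)
  nuc_px <- unique(cbind(sample(20:80, 300, TRUE), sample(20:80, 300, TRUE)))
  img[nuc_px] <- 250
  mask <- threshold_nuclei(img)
  expect_true(all(mask[nuc_px]))
  expect_equal(sum(mask), nrow(nuc_px))
  # threshold = mode + 2 sd of all pixels, far above the background tail
  thr <- attr(mask, "threshold")
  expect_equal(thr, 100 + 2 * sd(img), tolerance = 0.02)

  # shift equivariance: adding a constant moves the threshold, not the mask
  mask2 <- threshold_nuclei(img + 500)
  expect_identical(which(mask2), which(mask))

  expect_warning(m0 <- threshold_nuclei(matrix(7, 10, 10)), "constant")
  expect_false(any(m0))
})

test_that("mask cleaning removes specks but keeps real objects", {
  speck <- matrix(FALSE, 64, 64); speck[30, 30] <- TRUE
  expect_false(any(clean_mask(speck)))

  disk <- matrix(FALSE, 64, 64)
  yy <- outer(1:64 - 32, rep(1, 64)); xx <- outer(rep(1, 64), 1:64 - 32)
  disk[yy^2 + xx^2 <= 10^2] <- TRUE
  cleaned <- clean_mask(disk)
  expect_equal(sum(cleaned), sum(disk), tolerance = 0.1)

  empty <- matrix(FALSE, 32, 32)
  expect_identical(clean_mask(empty), empty)
})

test_that("watershed separates touching nuclei with distinct cores", {
  mk_disks <- function(centers, r = 20) {
    img <- matrix(FALSE, 140, 140)
    for (ctr in centers) {
      yy <- outer(1:140 - ctr[1], rep(1, 140))
      xx <- outer(rep(1, 140), 1:140 - ctr[2])
      img[yy^2 + xx^2 <= r^2] <- TRUE
    }
    img
  }
  # figure-eight: centers 1.5 radii apart -> 2 labels
  expect_equal(max(split_touching_nuclei(mk_disks(list(c(70, 55),
                                                       c(70, 85))))), 2)
  expect_equal(max(split_touching_nuclei(mk_disks(list(c(70, 70))))), 1)
  expect_equal(max(split_touching_nuclei(matrix(FALSE, 32, 32))), 0)
})

test_that("segmentation recovers generated counts", {
  # noise-free, non-touching: exact recovery
  for (s in 1:3) {
    gen0 <- image_gen_config(touching_fraction = 0, poisson_noise = FALSE,
                             noise_gaussian_sd = 0, tissue_margin_px = 30,
                             seed = s)
    pr <- generate_confocal_pair(list(true_nd = 3000), gen0)
    lab <- split_touching_nuclei(clean_mask(threshold_nuclei(pr$nucleus)))
    expect_equal(max(lab), pr$count)
  }
  # default noise and touching fraction: within +/- 5% over fields
  truth <- 0; meas <- 0
  for (s in 1:20) {
    gen1 <- image_gen_config(tissue_margin_px = 30, seed = 300 + s)
    pr <- generate_confocal_pair(list(true_nd = 3500), gen1)
    m <- measure_nd(pr$nucleus, pr$matrix, 0.2)
    truth <- truth + pr$count; meas <- meas + m$nucleus_count
  }
  expect_lt(abs(meas / truth - 1), 0.05)
})

test_that("measured ND increases with generator ND", {
  # as in the measurement protocol, each density is the mean of several
  # fields, which averages out the per-field Poisson count noise
  nds <- seq(800, 5000, length.out = 8)
  measured <- vapply(seq_along(nds), function(i) {
    mean(vapply(1:3, function(r) {
      gen <- image_gen_config(tissue_margin_px = 30, seed = 40 + 10 * i + r)
      pr <- generate_confocal_pair(list(true_nd = nds[i]), gen)
      measure_nd(pr$nucleus, pr$matrix, 0.2)$nd
    }, numeric(1)))
  }, numeric(1))
  expect_gte(cor(nds, measured, method = "spearman"), 0.95)
})

test_that("ND computation divides labels by the Otsu tissue area", {
  lab <- matrix(0L, 512, 512)
  lab[cbind(seq(10, 500, length.out = 42), seq(10, 500, length.out = 42))] <-
    1:42
  mat <- matrix(100, 512, 512)
  mat[7:506, 7:506] <- 1000  # 500 x 500 px tissue block
  m <- compute_nd(lab, mat, 0.2)
  expect_equal(m$nucleus_count, 42)
  expect_equal(m$tissue_area_mm2, 500 * 500 * (0.2 / 1000)^2)
  expect_equal(m$nd, 42 / 0.01)

  # halving the tissue area doubles ND
  mat2 <- matrix(100, 512, 512)
  mat2[7:506, 7:256] <- 1000
  m2 <- compute_nd(lab, mat2, 0.2)
  expect_equal(m2$nd / m$nd, m$tissue_area_mm2 / m2$tissue_area_mm2)

  # empty label image
  m0 <- compute_nd(matrix(0L, 512, 512), mat, 0.2)
  expect_equal(m0$nd, 0)
  expect_error(compute_nd(lab, matrix(100, 10, 10), 0.2), "shapes")
})

test_that("ND classes use the half-open 2000/3800 bins", {
  expect_equal(as.character(assign_nd_class(c(1500, 3000, 4000))),
               c("low", "medium", "high"))
  expect_equal(as.character(assign_nd_class(c(0, 2000, 3800))),
               c("low", "medium", "high"))
  expect_error(assign_nd_class(-5), "non-negative")
  # total and deterministic on a dense grid
  grid <- seq(0, 10000, by = 13)
  expect_false(anyNA(assign_nd_class(grid)))
})

test_that("the exponential decay fit recovers known constants", {
  truth <- nd_age_model(nd_floor = 1500, nd_amplitude = 30000, tau = 2.5)
  ages <- c(4.3, 4.5, 5, 6, 7, 9, 12, 20, 30, 56)
  fit <- fit_nd_age_decay(ages, nd_from_age(truth, ages))
  expect_equal(fit$model$nd_floor, 1500, tolerance = 0.01)
  expect_equal(fit$model$nd_amplitude, 30000, tolerance = 0.01)
  expect_equal(fit$model$tau, 2.5, tolerance = 0.01)

  # flat data: amplitude collapses toward zero
  flat <- fit_nd_age_decay(ages, rep(2000, length(ages)))
  expect_lt(flat$model$nd_amplitude, 0.01 * flat$model$nd_floor)

  expect_error(fit_nd_age_decay(c(1, 1, 2), c(1, 2, 3)), "at least 4")
})

test_that("a fit on the synthetic cohort reproduces the planted declines", {
  cohort <- generate_cohort()
  fit <- fit_nd_age_decay(cohort$age_months, cohort$true_nd)
  expect_equal(nd_percent_decline(fit$model, 4.3, 10), 72.5, tolerance = 0.07)
  expect_equal(nd_percent_decline(fit$model, 4.3, 56), 78.2, tolerance = 0.07)
})
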