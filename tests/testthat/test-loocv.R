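test_that("LOOCV folds satisfy the split invariants", {
  ids <- sprintf("S%02d", 1:22)
  folds <- make_loocv_folds(ids, seed = 3)
  expect_equal(nrow(folds), 22)
  expect_setequal(folds$test_sample_id, ids)  # every sample tests once
  for (i in seq_len(nrow(folds))) {
    tr <- folds$training_sample_ids[[i]]
    expect_length(tr, 20)
    expect_false(folds$test_sample_id[i] %in% tr)
    expect_false(folds$validation_sample_id[i] %in% tr)
    expect_false(folds$test_sample_id[i] == folds$validation_sample_id[i])
  }
  expect_identical(make_loocv_folds(ids, seed = 3), folds)
  expect_error(make_loocv_folds(c("a", "b"), 1), "at least 3")
})

test_that("accuracy is the confusion-matrix trace over its sum", {
  cm <- matrix(c(19, 1, 0, 0, 0, 0, 0, 0, 0), 3)
  expect_equal(accuracy(cm), 0.95)
  expect_equal(accuracy(diag(c(5, 5, 5))), 1)
  expect_equal(accuracy(matrix(1, 3, 3)), 1 / 3)
  expect_error(accuracy(matrix(0, 3, 3)), "empty")
})

test_that("the hyperparameter grid is the 10 x 4 geometric design", {
  g <- hyper_grid()
  expect_equal(nrow(g), 40)
  lrs <- sort(unique(g$learning_rate))
  expect_length(lrs, 10)
  expect_equal(lrs[1], 1e-4)
  expect_equal(lrs[10], 1e-2)
  expect_equal(diff(log(lrs)), rep(log(100) / 9, 9), tolerance = 1e-9)
  expect_setequal(unique(g$min_delta), c(0.001, 0.003, 0.005, 0.007))
})

test_that("grid search selects by accuracy then validation loss", {
  dataset <- tiny_dataset()
  folds <- make_loocv_folds(unique(dataset$sample_id), seed = 2)
  grid <- data.frame(learning_rate = c(0.002, 0.01),
                     min_delta = c(0.001, 0.001))
  set.seed(31)
  gs <- grid_search_fold(folds[1, ], dataset, grid,
                         base_config = training_config(max_epochs = 300))
  tab <- gs$search
  best_acc <- max(tab$validation_accuracy)
  expect_equal(gs$validation_accuracy, best_acc)
  contenders <- tab[tab$validation_accuracy == best_acc, ]
  expect_equal(gs$validation_loss, min(contenders$validation_loss))
  # degenerate one-point grid returns that configuration
  set.seed(32)
  g1 <- grid_search_fold(folds[1, ], dataset, grid[1, , drop = FALSE],
                         base_config = training_config(max_epochs = 100))
  expect_equal(g1$config$learning_rate, 0.002)
  expect_error(grid_search_fold(folds[1, ], dataset, grid[0, , drop = FALSE]),
               "empty")
})

test_that("LOOCV on a separable cohort reaches the expected ceiling", {
  # per-fold hyperparameter search makes the protocol robust to the
  # occasional dead-initialization training run
  dataset <- tiny_dataset()
  grid <- hyper_grid(learning_rates = c(0.002, 0.005, 0.01),
                     min_deltas = c(0.001, 0.003))
  rep <- run_loocv(dataset, grid = grid, downsample_K = 50, seed = 5)
  expect_equal(nrow(rep$folds), 9)
  expect_equal(sum(rep$confusion), nrow(dataset$x))
  expect_equal(rep$accuracy, accuracy(rep$confusion))
  expect_gte(rep$accuracy, 0.95)
  # one hyperparameter record per fold
  expect_equal(nrow(unique(rep$folds[, c("fold", "learning_rate",
                                         "min_delta")])), 9)
})

test_that("LOOCV reports are reproducible from the master seed", {
  dataset <- tiny_dataset(n_acquisitions = 3)
  grid <- data.frame(learning_rate = 0.01, min_delta = 0.003)
  r1 <- run_loocv(dataset, grid = grid, downsample_K = 100, seed = 11)
  r2 <- run_loocv(dataset, grid = grid, downsample_K = 100, seed = 11)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$folds, r2$folds)
})

test_that("Fisher's LSD flags only genuinely different accuracy groups", {
  same <- list(a = c(0.9, 0.95, 1), b = c(0.9, 0.95, 1))
  cmp0 <- fisher_lsd(same)
  expect_length(cmp0$significant_pairs, 0)
  diff_ <- list(a = c(0.2, 0.25, 0.3, 0.22), b = c(0.21, 0.26, 0.31, 0.24),
                c = c(0.9, 0.95, 0.92, 0.97))
  cmp <- fisher_lsd(diff_)
  expect_setequal(cmp$significant_pairs, c("a-c", "b-c"))
  expect_lt(cmp$p_value, 0.01)
})

test_that("wavelength sensitivity finds a window-localized signal", {
  gen_loc <- spectrum_gen_config(signal_band_nm = c(900, 1100),
                                 slope_coupling = 0.16,
                                 oscillation_coupling = 0.1)
  cfg <- tiny_cohort_config(n_acquisitions = 4)
  cohort <- generate_cohort(cfg)
  raw <- generate_cohort_spectra(cohort, gen_loc, 4, seed = 21)
  classes <- setNames(cohort$nd_class, cohort$sample_id)
  res <- wavelength_sensitivity_experiment(
    raw, classes, base_config = training_config(max_epochs = 400),
    downsample_K = 20, seed = 21)
  accs <- vapply(res$accuracies, mean, numeric(1))
  expect_gt(accs[["900-1100 nm"]], max(accs[1:2]))
  # the informative window is significantly better than both dead windows
  sig <- res$comparison$significant_pairs
  expect_true(any(grepl("900-1100", sig)))
})

test_that("resolution schedule is geometric and infeasible scales error", {
  Ks <- eval(formals(resolution_sensitivity_experiment)$K_schedule)
  expect_length(Ks, 15)
  expect_equal(Ks[1], 10)
  expect_equal(Ks[15], 1000)
  expect_equal(diff(log(Ks)), rep(diff(log(c(10, 1000))) / 14, 14),
               tolerance = 1e-9)

  dataset <- tiny_dataset(n_acquisitions = 2)
  expect_error(
    resolution_sensitivity_experiment(dataset,
                                      base_config = training_config(
                                        max_epochs = 10, patience_epochs = 10)),
    "minimum input")
})

test_that("accuracy survives coarse resolution reduction on separable data", {
  # fixed-rate training sessions occasionally collapse at initialization
  # (all-or-nothing per-fold accuracies, as the protocol's large reported
  # SDs reflect), so the chance-level comparison pools three seeded runs
  dataset <- tiny_dataset()
  correct <- 0; total <- 0
  for (s in 9:11) {
    res <- suppressMessages(resolution_sensitivity_experiment(
      dataset, K_schedule = c(112),
      base_config = training_config(max_epochs = 400),
      on_infeasible = "skip", seed = s))
    expect_equal(res$table$input_length, 65)
    correct <- correct + sum(diag(res$reports[[1]]$confusion))
    total <- total + sum(res$reports[[1]]$confusion)
  }
  # even at the coarsest feasible scale the broad spectral features keep
  # the classifier above the 99% binomial chance band around 1/3
  expect_gt(correct / total, qbinom(0.995, total, 1 / 3) / total)
})
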