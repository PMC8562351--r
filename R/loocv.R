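#' Leave-one-out folds with a random validation sample
#'
#' One fold per tissue sample: the held-out sample is the test set and a
#' second sample, drawn uniformly from the remainder, is the validation set
#' used for hyperparameter selection; the remaining samples train the
#' network.
#'
#' @param sample_ids Character vector of distinct sample ids (>= 3).
#' @param seed Integer seed governing the validation draws.
#' @return Data frame with `fold`, `test_sample_id`, `validation_sample_id`
#'   and a list column `training_sample_ids`.
#' @export
make_loocv_folds <- function(sample_ids, seed = 1L) {
  sample_ids <- unique(as.character(sample_ids))
  if (length(sample_ids) < 3) stop("need at least 3 samples for LOOCV")
  set.seed(seed)
  folds <- lapply(seq_along(sample_ids), function(i) {
    test <- sample_ids[i]
    rest <- setdiff(sample_ids, test)
    val <- sample(rest, 1)
    list(fold = i, test_sample_id = test, validation_sample_id = val,
         training_sample_ids = setdiff(rest, val))
  })
  out <- data.frame(
    fold = vapply(folds, `[[`, integer(1), "fold"),
    test_sample_id = vapply(folds, `[[`, character(1), "test_sample_id"),
    validation_sample_id = vapply(folds, `[[`, character(1),
                                  "validation_sample_id"),
    stringsAsFactors = FALSE
  )
  out$training_sample_ids <- lapply(folds, `[[`, "training_sample_ids")
  out
}

#' Classification accuracy from a confusion matrix
#'
#' Accuracy is the number of correct predictions over the total number of
#' predictions, i.e. the trace of the confusion matrix over its sum.
#'
#' @param confusion Square matrix of counts indexed (true, predicted).
#' @return Fraction in `[0, 1]`.
#' @export
accuracy <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(confusion)) / total
}

#' The 10 x 4 hyperparameter grid
#'
#' Ten learning rates geometrically spaced over `[1e-4, 1e-2]` (endpoints
#' included) crossed with the four minimum-delta values 0.001, 0.003, 0.005
#' and 0.007.
#'
#' @param learning_rates Numeric vector (default the 10-point geometric
#'   sequence).
#' @param min_deltas Numeric vector (default `c(0.001, 0.003, 0.005,
#'   0.007)`).
#' @return Data frame with one row per combination.
#' @export
hyper_grid <- function(learning_rates = exp(seq(log(1e-4), log(1e-2),
                                                length.out = 10)),
                       min_deltas = c(0.001, 0.003, 0.005, 0.007)) {
  stopifnot(all(diff(learning_rates) > 0))
  expand.grid(learning_rate = learning_rates, min_delta = min_deltas,
              KEEP.OUT.ATTRS = FALSE)
}

subset_rows <- function(dataset, ids) {
  keep <- dataset$sample_id %in% ids
  list(x = dataset$x[keep, , drop = FALSE],
       y = dataset$class[keep],
       sample_id = dataset$sample_id[keep])
}

#' Grid search over one LOOCV fold
#'
#' Trains one network per grid point on the fold's training spectra, scores
#' each on the validation sample, and selects the configuration with the
#' highest validation accuracy, breaking ties by the lowest validation loss
#' (and then by grid order, for determinism).
#'
#' @param fold One row of [make_loocv_folds()] output (data frame or list
#'   with `test_sample_id`, `validation_sample_id`, `training_sample_ids`).
#' @param dataset List with `x` (spectra matrix), `class` (factor of
#'   per-spectrum labels) and `sample_id` (per-spectrum ids).
#' @param grid Data frame from [hyper_grid()].
#' @param spec A [network_spec()].
#' @param base_config A [training_config()] providing patience, epoch
#'   budget and batch size; learning rate and min delta come from the grid.
#' @return List with `config` (winning [training_config()]), `model`
#'   (trained winner), `validation_accuracy`, `validation_loss` and the
#'   per-grid-point `search` table.
#' @export
grid_search_fold <- function(fold, dataset, grid = hyper_grid(),
                             spec = network_spec(),
                             base_config = training_config()) {
  if (nrow(grid) == 0) stop("empty hyperparameter grid")
  train_ids <- unlist(fold$training_sample_ids)
  stopifnot(!fold$test_sample_id %in% train_ids,
            !fold$validation_sample_id %in% train_ids,
            fold$test_sample_id != fold$validation_sample_id)
  tr <- subset_rows(dataset, train_ids)
  va <- subset_rows(dataset, fold$validation_sample_id)
  stopifnot(length(intersect(tr$sample_id, va$sample_id)) == 0)
  results <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- training_config(learning_rate = grid$learning_rate[g],
                           min_delta = grid$min_delta[g],
                           patience_epochs = base_config$patience_epochs,
                           max_epochs = base_config$max_epochs,
                           batch_size = base_config$batch_size)
    model <- build_network(ncol(dataset$x), spec)
    model <- train_with_early_stopping(model, tr$x, tr$y, cfg)
    pv <- predict_classes(model, va$x, va$y)
    results[[g]] <- list(model = model, config = cfg,
                         val_acc = pv$accuracy, val_loss = pv$loss)
  }
  acc <- vapply(results, `[[`, numeric(1), "val_acc")
  loss <- vapply(results, `[[`, numeric(1), "val_loss")
  best <- order(-acc, loss)[1]
  list(config = results[[best]]$config,
       model = results[[best]]$model,
       validation_accuracy = acc[best],
       validation_loss = loss[best],
       search = cbind(grid, validation_accuracy = acc,
                      validation_loss = loss))
}

#' Nested leave-one-out cross-validation of the CNN classifier
#'
#' The full supervised evaluation protocol: per fold, a hyperparameter grid
#' search scored on the fold's validation sample, then prediction of the
#' held-out sample's spectra with the winning network. Test predictions are
#' aggregated into a 3 x 3 confusion matrix; overall accuracy is its trace
#' over its sum, and per-fold accuracies (over each fold's test spectra) are
#' reported as mean and SD. Training never sees test or validation spectra;
#' this is asserted at run time.
#'
#' @param dataset List with `x` (spectra matrix), `class` (factor of
#'   per-spectrum ND class labels) and `sample_id`.
#' @param grid Data frame from [hyper_grid()]; a single-row grid reproduces
#'   the fixed-hyperparameter protocol.
#' @param spec A [network_spec()].
#' @param base_config A [training_config()] (patience/epochs/batch).
#' @param downsample_K Optional resolution-reduction factor applied to the
#'   spectra before training (default 50; use `NULL` to skip).
#' @param seed Master seed: governs fold validation draws, weight
#'   initialization and batch shuffling.
#' @return A `loocv_report` list with `folds` (per-fold choices and
#'   accuracies), `confusion`, `accuracy`, `fold_accuracy_mean`,
#'   `fold_accuracy_sd` and `predictions`.
#' @export
run_loocv <- function(dataset, grid = hyper_grid(), spec = network_spec(),
                      base_config = training_config(),
                      downsample_K = 50, seed = 1L) {
  stopifnot(!anyNA(dataset$class), nlevels(as.factor(dataset$class)) >= 1)
  dataset$class <- as.factor(dataset$class)
  if (!is.null(downsample_K) && downsample_K > 1)
    dataset$x <- t(apply(dataset$x, 1, downsample1d, K = downsample_K))
  folds <- make_loocv_folds(unique(dataset$sample_id), seed = seed)
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max - 1L, nrow(folds))
  fold_rows <- vector("list", nrow(folds))
  preds <- vector("list", nrow(folds))
  lev <- levels(dataset$class)
  confusion <- matrix(0L, length(lev), length(lev),
                      dimnames = list(true = lev, predicted = lev))
  for (f in seq_len(nrow(folds))) {
    fold <- folds[f, ]
    set.seed(fold_seeds[f])
    gs <- grid_search_fold(fold, dataset, grid, spec, base_config)
    te <- subset_rows(dataset, fold$test_sample_id)
    # leakage assertion: test/validation spectra never seen in training
    train_ids <- unlist(fold$training_sample_ids)
    if (fold$test_sample_id %in% train_ids ||
        fold$validation_sample_id %in% train_ids)
      stop("leakage detected in fold ", f)
    pt <- predict_classes(gs$model, te$x, te$y)
    confusion <- confusion + table(factor(te$y, levels = lev),
                                   factor(pt$labels, levels = lev))
    fold_rows[[f]] <- data.frame(
      fold = fold$fold, test_sample_id = fold$test_sample_id,
      validation_sample_id = fold$validation_sample_id,
      learning_rate = gs$config$learning_rate,
      min_delta = gs$config$min_delta,
      validation_accuracy = gs$validation_accuracy,
      validation_loss = gs$validation_loss,
      test_accuracy = pt$accuracy,
      stringsAsFactors = FALSE
    )
    preds[[f]] <- data.frame(sample_id = te$sample_id,
                             true = te$y, predicted = pt$labels,
                             stringsAsFactors = FALSE)
  }
  folds_df <- do.call(rbind, fold_rows)
  structure(list(
    folds = folds_df,
    confusion = confusion,
    accuracy = accuracy(confusion),
    fold_accuracy_mean = mean(folds_df$test_accuracy),
    fold_accuracy_sd = stats::sd(folds_df$test_accuracy),
    predictions = do.call(rbind, preds)
  ), class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %d folds | aggregate accuracy %.2f%% | ",
              nrow(x$folds), 100 * x$accuracy),
      sprintf("per-fold %.1f +/- %.1f%%\n",
              100 * x$fold_accuracy_mean, 100 * x$fold_accuracy_sd))
  print(x$confusion)
  invisible(x)
}

#' One-way ANOVA with Fisher's least-significant-difference comparisons
#'
#' Pairwise comparisons use the pooled ANOVA mean-square error and
#' unadjusted t tests at level `alpha` (Fisher's LSD).
#'
#' @param groups Named list of numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @return A list with `F_statistic`, `p_value`, `pairs` (data frame with
#'   per-pair difference, t, p) and `significant_pairs`.
#' @export
fisher_lsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  ns <- vapply(groups, length, integer(1))
  dat <- data.frame(value = unlist(groups, use.names = FALSE),
                    group = factor(rep(names(groups), ns),
                                   levels = names(groups)))
  an <- summary(stats::aov(value ~ group, data = dat))[[1]]
  mse <- an["Residuals", "Mean Sq"]
  df <- an["Residuals", "Df"]
  means <- vapply(groups, mean, numeric(1))
  cmb <- utils::combn(names(groups), 2)
  pairs <- data.frame(
    group1 = cmb[1, ], group2 = cmb[2, ],
    difference = means[cmb[1, ]] - means[cmb[2, ]],
    stringsAsFactors = FALSE
  )
  pairs$t <- pairs$difference /
    sqrt(mse * (1 / ns[pairs$group1] + 1 / ns[pairs$group2]))
  pairs$p <- 2 * stats::pt(-abs(pairs$t), df)
  rownames(pairs) <- NULL
  list(F_statistic = an["group", "F value"],
       p_value = an["group", "Pr(>F)"],
       pairs = pairs,
       significant_pairs = paste(pairs$group1, pairs$group2,
                                 sep = "-")[pairs$p < alpha],
       alpha = alpha)
}

#' Wavelength-range sensitivity of the classifier
#'
#' Runs the fixed-hyperparameter LOOCV (learning rate 0.005, minimum delta
#' 0.001) separately on spectra restricted to each wavelength window
#' (windowing applies per fiber, before concatenation), then compares the
#' per-fold accuracy lists by one-way ANOVA with Fisher's LSD.
#'
#' @param raw_records List of raw per-fiber [spectrum_record()]s.
#' @param sample_classes Named factor of ND classes, names = sample ids.
#' @param windows List of `c(lo, hi)` windows (default the three 200-nm
#'   ranges).
#' @param spec A [network_spec()].
#' @param base_config A [training_config()]; its learning rate and min
#'   delta are used for every network.
#' @param filter A [filter_spec()].
#' @param downsample_K Resolution reduction applied after concatenation
#'   (default 50).
#' @param seed Master seed.
#' @return A list with `reports` (per-window `loocv_report`s), `accuracies`
#'   (per-window per-fold lists) and `comparison` (Fisher's LSD).
#' @export
wavelength_sensitivity_experiment <- function(raw_records, sample_classes,
                                              windows = list(c(500, 700),
                                                             c(700, 900),
                                                             c(900, 1100)),
                                              spec = network_spec(),
                                              base_config = training_config(),
                                              filter = filter_spec(),
                                              downsample_K = 50,
                                              seed = 1L) {
  grid <- data.frame(learning_rate = base_config$learning_rate,
                     min_delta = base_config$min_delta)
  reports <- lapply(windows, function(w) {
    conc <- preprocess_spectra(raw_records, filter, window = w)
    sm <- spectra_to_matrix(conc)
    dataset <- list(x = sm$x, sample_id = sm$meta$sample_id,
                    class = sample_classes[sm$meta$sample_id])
    run_loocv(dataset, grid = grid, spec = spec,
              base_config = base_config, downsample_K = downsample_K,
              seed = seed)
  })
  names(reports) <- vapply(windows, function(w)
    sprintf("%g-%g nm", w[1], w[2]), character(1))
  accs <- lapply(reports, function(r) r$folds$test_accuracy)
  list(reports = reports, accuracies = accs,
       comparison = fisher_lsd(accs))
}

#' Resolution-reduction sensitivity of the classifier
#'
#' Runs the fixed-hyperparameter LOOCV on spectra reduced by each scale of a
#' 15-point geometric schedule over `[10, 1000]`. Scales that make the
#' spectrum shorter than the network's minimum input length raise an error
#' naming the limit (default) or are skipped.
#'
#' @param dataset List with `x` (concatenated spectra matrix), `class`,
#'   `sample_id`.
#' @param K_schedule Numeric vector of scales (default the 15-point
#'   geometric schedule over `[10, 1000]`).
#' @param spec A [network_spec()].
#' @param base_config A [training_config()].
#' @param on_infeasible `"error"` or `"skip"`.
#' @param seed Master seed.
#' @return A list with `table` (data frame `K`, `accuracy`,
#'   `fold_accuracy_mean`, `fold_accuracy_sd`) and `reports`.
#' @export
resolution_sensitivity_experiment <- function(dataset,
                                              K_schedule =
                                                exp(seq(log(10), log(1000),
                                                        length.out = 15)),
                                              spec = network_spec(),
                                              base_config = training_config(),
                                              on_infeasible = c("error",
                                                                "skip"),
                                              seed = 1L) {
  on_infeasible <- match.arg(on_infeasible)
  min_len <- cnn_min_input_length(spec)
  n <- ncol(dataset$x)
  lens <- vapply(K_schedule, function(K) max(2, round(n / K)), numeric(1))
  bad <- lens < min_len
  if (any(bad)) {
    msg <- paste0("scales ", paste(signif(K_schedule[bad], 4),
                                   collapse = ", "),
                  " reduce the spectrum below the network's minimum input ",
                  "length of ", min_len, " samples")
    if (on_infeasible == "error") stop(msg) else message("skipping: ", msg)
  }
  ks <- K_schedule[!bad]
  grid <- data.frame(learning_rate = base_config$learning_rate,
                     min_delta = base_config$min_delta)
  reports <- lapply(ks, function(K)
    run_loocv(dataset, grid = grid, spec = spec,
              base_config = base_config, downsample_K = K, seed = seed))
  tab <- data.frame(
    K = ks,
    input_length = vapply(ks, function(K) max(2, round(n / K)), numeric(1)),
    accuracy = vapply(reports, `[[`, numeric(1), "accuracy"),
    fold_accuracy_mean = vapply(reports, `[[`, numeric(1),
                                "fold_accuracy_mean"),
    fold_accuracy_sd = vapply(reports, `[[`, numeric(1), "fold_accuracy_sd")
  )
  list(table = tab, reports = reports)
}
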