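#' Specification of the compact spectrum-classification network
#'
#' The fixed layer stack is: three 1D convolutions (3 filters, kernel 5,
#' stride 2, ReLU) with a 2/2 max-pool (no padding) after the second and
#' third convolutions, a flatten, and a dense 3-unit projection with softmax
#' producing the low/medium/high class probabilities. Only the convolution
#' padding is configurable; `"valid"` (no padding) is the default,
#' consistent with the unpadded pooling stages.
#'
#' @param conv_padding `"valid"` or `"same"`.
#' @param n_classes Number of output classes (fixed at 3).
#' @return A `network_spec` list.
#' @export
network_spec <- function(conv_padding = c("valid", "same"), n_classes = 3) {
  conv_padding <- match.arg(conv_padding)
  stopifnot(n_classes == 3)
  structure(list(conv_padding = conv_padding, n_classes = 3L,
                 n_filters = 3L, kernel = 5L, stride = 2L,
                 pool = 2L, pool_stride = 2L),
            class = "network_spec")
}

#' Per-layer output lengths of the network
#'
#' Applies the layer-shape recurrence (conv: `floor((L - 5)/2) + 1` for
#' valid padding, `ceiling(L / 2)` for same padding; pool: `floor(L / 2)`)
#' and errors naming the first layer whose output would be empty.
#'
#' @param input_length Length of the input spectrum.
#' @param spec A [network_spec()].
#' @return Named integer vector with elements `conv1`, `conv2`, `pool1`,
#'   `conv3`, `pool2`, `flatten`.
#' @export
cnn_layer_shapes <- function(input_length, spec = network_spec()) {
  conv_out <- function(L) {
    if (spec$conv_padding == "same") ceiling(L / 2)
    else floor((L - spec$kernel) / spec$stride) + 1
  }
  pool_out <- function(L) floor(L / spec$pool)
  L <- as.integer(input_length)
  out <- integer(0)
  for (layer in c("conv1", "conv2", "pool1", "conv3", "pool2")) {
    L <- if (startsWith(layer, "conv")) conv_out(L) else pool_out(L)
    if (L < 1)
      stop("input length ", input_length, " is too short: layer ", layer,
           " would have empty output")
    out[layer] <- as.integer(L)
  }
  out["flatten"] <- out["pool2"] * spec$n_filters
  out
}

#' Smallest input length the network accepts
#'
#' @param spec A [network_spec()].
#' @return Integer minimum input length.
#' @export
cnn_min_input_length <- function(spec = network_spec()) {
  for (L in 2:4096) {
    ok <- tryCatch({ cnn_layer_shapes(L, spec); TRUE },
                   error = function(e) FALSE)
    if (ok) return(L)
  }
  stop("no feasible input length found")
}

#' Build an untrained network
#'
#' Initializes the weights with Glorot-uniform draws (biases zero) for the
#' given input length. Initialization consumes the R random number stream,
#' so wrap in `set.seed()` for reproducible weights.
#'
#' @param input_length Spectrum length the network will consume.
#' @param spec A [network_spec()].
#' @return A `cnn_model` list with `spec`, `input_length`, `shapes`,
#'   `weights` and (after training) `history`, `best_epoch`,
#'   `class_levels`.
#' @export
build_network <- function(input_length, spec = network_spec()) {
  shapes <- cnn_layer_shapes(input_length, spec)
  k <- spec$kernel; nf <- spec$n_filters
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  nflat <- shapes[["flatten"]]
  weights <- list(
    w1 = glorot(k, nf, k, k * nf), b1 = numeric(nf),
    w2 = glorot(k * nf, nf, k * nf, k * nf), b2 = numeric(nf),
    w3 = glorot(k * nf, nf, k * nf, k * nf), b3 = numeric(nf),
    wd = glorot(nflat, spec$n_classes, nflat, spec$n_classes),
    bd = numeric(spec$n_classes)
  )
  structure(list(spec = spec, input_length = as.integer(input_length),
                 shapes = shapes, weights = weights),
            class = "cnn_model")
}

#' Count the trainable parameters of a model
#'
#' Counts the elements of the stored weight and bias arrays; tests cross-
#' check this against the closed-form layer-shape recurrence.
#'
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' Training configuration
#'
#' @param learning_rate Adam step size (> 0).
#' @param min_delta Smallest epoch-loss improvement the early-stopping
#'   monitor counts as progress (default 0.001).
#' @param patience_epochs Epochs without sufficient improvement before
#'   training stops (default 100).
#' @param max_epochs Epoch budget (default 1000).
#' @param batch_size Minibatch size (default 32).
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 0.005, min_delta = 0.001,
                            patience_epochs = 100, max_epochs = 1000,
                            batch_size = 32) {
  stopifnot(learning_rate > 0, min_delta > 0,
            patience_epochs <= max_epochs)
  structure(list(learning_rate = learning_rate, min_delta = min_delta,
                 patience_epochs = as.integer(patience_epochs),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size)),
            class = "training_config")
}

#' Train a network with early stopping and best-weight restoration
#'
#' Minimizes the categorical cross-entropy (computed from the logits) with
#' Adam. The monitored quantity is the running training loss of each epoch.
#' Weights are checkpointed whenever the loss decreases and the
#' checkpointed minimum-loss weights are restored at the end; training stops
#' once the loss has not improved by more than `min_delta` for
#' `patience_epochs` epochs, or at `max_epochs`. Deterministic given the R
#' RNG state (use `set.seed()`).
#'
#' @param model A `cnn_model` from [build_network()].
#' @param x Numeric matrix of training spectra (rows), `ncol(x)` equal to
#'   the model input length.
#' @param y Factor (or vector coercible to one) of class labels.
#' @param config A [training_config()].
#' @return The trained `cnn_model` with `history` (per-epoch loss),
#'   `best_epoch`, `best_loss` and `class_levels`.
#' @export
train_with_early_stopping <- function(model, x, y, config = training_config()) {
  if (nrow(x) == 0) stop("empty training set")
  if (ncol(x) != model$input_length)
    stop("spectra length ", ncol(x), " does not match model input length ",
         model$input_length)
  y <- as.factor(y)
  if (nlevels(y) > model$spec$n_classes)
    stop("more classes than network outputs")
  if (length(unique(y)) < 2)
    warning("single-class training set: classifier is degenerate")
  fit <- .cnn_train(model$weights, x, as.integer(y) - 1L,
                    model$spec$conv_padding == "same",
                    config$learning_rate, config$min_delta,
                    config$patience_epochs, config$max_epochs,
                    config$batch_size)
  model$weights <- fit$weights
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$best_loss <- fit$best_loss
  model$epochs_run <- fit$epochs_run
  model$class_levels <- levels(y)
  model
}

#' Predict class labels and probabilities for spectra
#'
#' @param model A trained `cnn_model`.
#' @param x Numeric matrix of spectra, `ncol(x)` equal to the model input
#'   length.
#' @param y Optional true labels; if given, accuracy and mean cross-entropy
#'   are included.
#' @return A list with `labels` (argmax class, ties toward the lower class
#'   index), `probabilities` (rows summing to 1) and, when `y` is supplied,
#'   `accuracy` and `loss`.
#' @export
predict_classes <- function(model, x, y = NULL) {
  if (ncol(x) != model$input_length)
    stop("spectra length ", ncol(x), " does not match model input length ",
         model$input_length)
  probs <- .cnn_predict(model$weights, x,
                        model$spec$conv_padding == "same")
  lev <- model$class_levels %||% as.character(seq_len(ncol(probs)))
  idx <- max.col(probs, ties.method = "first")
  labels <- factor(lev[idx], levels = lev)
  out <- list(labels = labels, probabilities = probs)
  if (!is.null(y)) {
    y <- factor(y, levels = lev)
    out$accuracy <- mean(labels == y)
    out$loss <- -mean(log(pmax(probs[cbind(seq_len(nrow(probs)),
                                           as.integer(y))], 1e-15)))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a trained model as portable JSON
#'
#' Stores the network specification, shapes, class levels and weights in a
#' single JSON file.
#'
#' @param model A `cnn_model`.
#' @param path File path.
#' @return `load_cnn_model()` returns the restored `cnn_model`.
#' @export
save_cnn_model <- function(model, path) {
  payload <- list(
    spec = unclass(model$spec),
    input_length = model$input_length,
    class_levels = model$class_levels,
    weights = lapply(model$weights, function(w)
      if (is.matrix(w)) list(dim = dim(w), data = as.numeric(w))
      else list(dim = length(w), data = as.numeric(w)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_cnn_model
#' @export
load_cnn_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- network_spec(p$spec$conv_padding)
  model <- build_network(p$input_length, spec)
  model$weights <- lapply(p$weights, function(w) {
    if (length(w$dim) == 2) matrix(w$data, w$dim[1], w$dim[2])
    else as.numeric(w$data)
  })
  model$class_levels <- p$class_levels
  model
}
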