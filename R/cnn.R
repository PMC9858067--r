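#' 1D-CNN configuration
#'
#' Architecture and training hyperparameters of the one-dimensional
#' convolutional network. The layer stack is fixed by construction:
#' `Conv1D(filters, kernel, stride 1, ReLU) -> MaxPool(3) ->
#' Conv1D(filters, kernel, 1, ReLU) -> MaxPool(3) -> Flatten ->
#' Dense(dense_units, ReLU) -> Dropout -> Dense(n_classes, ReLU) ->
#' Softmax`. Convolutions are "valid" (no padding); pooling is
#' non-overlapping (stride = pool size). The printed architecture places a
#' ReLU on the 3-unit layer ahead of the softmax; that variant is
#' available as `relu_output = TRUE`, but the default head is the standard
#' linear-logit softmax, because a ReLU there lets all three logits die
#' together (the gradient mask then blocks every learning signal) on
#' low-contrast inputs, which the vignette documents.
#'
#' Training uses categorical cross-entropy with the Adam optimizer.
#'
#' @param conv_filters filters per convolutional layer (64).
#' @param conv_kernel kernel size (3).
#' @param pool_size pooling window and stride (3).
#' @param dense_units units of the fully connected feature layer (64).
#' @param n_classes output classes (3).
#' @param dropout_rate dropout fraction after the dense feature layer,
#'   in `[0, 1)`; default 0.5.
#' @param epochs training epochs; default 20.
#' @param batch_size mini-batch size; default 32.
#' @param learning_rate Adam step size; default 1e-3.
#' @param relu_output apply ReLU to the final 3-unit layer before the
#'   softmax (default FALSE; TRUE reproduces the printed architecture
#'   literally but is prone to dead-logit collapse).
#' @param seed integer seed for weight initialisation, batch shuffling and
#'   dropout masks.
#' @return A `cnn_config` list.
#' @export
cnn_config <- function(conv_filters = 64L, conv_kernel = 3L, pool_size = 3L,
                       dense_units = 64L, n_classes = 3L,
                       dropout_rate = 0.5, epochs = 20L, batch_size = 32L,
                       learning_rate = 1e-3, relu_output = FALSE,
                       seed = 1L) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            conv_kernel >= 1, pool_size >= 1, epochs >= 0, batch_size >= 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 conv_kernel = as.integer(conv_kernel),
                 pool_size = as.integer(pool_size),
                 dense_units = as.integer(dense_units),
                 n_classes = as.integer(n_classes),
                 dropout_rate = dropout_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 relu_output = isTRUE(relu_output),
                 seed = as.integer(seed)),
            class = "cnn_config")
}

#' Per-layer output lengths of the 1D-CNN
#'
#' Valid convolution maps a length L to `L - kernel + 1`; non-overlapping
#' pooling maps L to `floor(L / pool)`. For the default fused input of 639
#' variables: 639 -> 637 -> 212 -> 210 -> 70 -> 4480 (flatten) -> 64 -> 3.
#'
#' @param input_length number of input variables.
#' @param cfg a [cnn_config()].
#' @return Named integer vector: `input`, `conv1`, `pool1`, `conv2`,
#'   `pool2`, `flatten`, `dense`, `output`.
#' @export
cnn_layer_sizes <- function(input_length, cfg = cnn_config()) {
  input_length <- as.integer(input_length)
  k <- cfg$conv_kernel; p <- cfg$pool_size
  conv1 <- input_length - k + 1L
  if (conv1 < 1L) stop("input length ", input_length,
                       " too short for a kernel-", k, " convolution")
  pool1 <- conv1 %/% p
  if (pool1 < 1L) stop("length ", conv1, " too short for pool size ", p)
  conv2 <- pool1 - k + 1L
  if (conv2 < 1L) stop("length ", pool1,
                       " too short for the second convolution (kernel ", k, ")")
  pool2 <- conv2 %/% p
  if (pool2 < 1L) stop("length ", conv2,
                       " too short for the second pooling stage")
  c(input = as.integer(input_length), conv1 = conv1, pool1 = pool1,
    conv2 = conv2, pool2 = pool2,
    flatten = pool2 * cfg$conv_filters,
    dense = cfg$dense_units, output = cfg$n_classes)
}

#' Build an untrained 1D-CNN
#'
#' Validates the layer arithmetic for the given input length and
#' initialises the weights (He-scaled normal draws, small positive biases;
#' seeded by `cfg$seed`).
#'
#' @param input_length number of input variables.
#' @param cfg a [cnn_config()].
#' @return An object of class `cnn1d` with empty training history.
#' @export
build_cnn <- function(input_length, cfg = cnn_config()) {
  sizes <- cnn_layer_sizes(input_length, cfg)
  set.seed(cfg$seed)
  nf <- cfg$conv_filters; k <- cfg$conv_kernel
  he <- function(nr, nc, fan_in)
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  w <- list(
    W1 = he(k, nf, k), b1 = rep(0.01, nf),
    W2 = he(k * nf, nf, k * nf), b2 = rep(0.01, nf),
    W3 = he(sizes[["flatten"]], cfg$dense_units, sizes[["flatten"]]),
    b3 = rep(0.01, cfg$dense_units),
    W4 = he(cfg$dense_units, cfg$n_classes, cfg$dense_units),
    b4 = rep(0.1, cfg$n_classes))
  structure(list(cfg = cfg, input_length = as.integer(input_length),
                 sizes = sizes, weights = w,
                 history = empty_history(), trained = FALSE),
            class = c("cnn1d", "mildew_model"))
}

empty_history <- function() {
  data.frame(epoch = integer(0), train_loss = numeric(0),
             train_acc = numeric(0), test_loss = numeric(0),
             test_acc = numeric(0))
}

#' Fit the 1D-CNN on a spectral dataset
#'
#' Builds (or reuses) the network and trains it by minimising categorical
#' cross-entropy with Adam. Weight initialisation, mini-batch shuffling and
#' dropout masks all derive from `cfg$seed`, so a fit is exactly
#' reproducible run-to-run under single-threaded linear algebra. Per-epoch
#' training loss/accuracy (running mini-batch averages) are recorded in the
#' history; when `test` is supplied its loss/accuracy are evaluated each
#' epoch as well, giving the accuracy/loss curves used to diagnose the
#' model.
#'
#' @param train a [spectral_dataset()]; labels must be grade codes 0..2.
#' @param cfg a [cnn_config()].
#' @param test optional [spectral_dataset()] monitored during training.
#' @return A fitted `cnn1d` object.
#' @export
fit_cnn <- function(train, cfg = cnn_config(), test = NULL) {
  model <- build_cnn(ncol(train$X), cfg)   # seeds the RNG, draws init weights
  n <- nrow(train$X)
  if (n == 0) stop("empty training set")
  if (!all(train$y %in% (seq_len(cfg$n_classes) - 1L)))
    stop("labels outside 0..", cfg$n_classes - 1L)
  if (cfg$epochs == 0L) return(model)
  has_test <- !is.null(test) && nrow(test$X) > 0
  fit <- cnn_train_cpp(train$X, train$y, model$weights,
                       cfg$epochs, cfg$batch_size, cfg$learning_rate,
                       cfg$dropout_rate, cfg$relu_output,
                       cfg$conv_kernel, cfg$pool_size, cfg$n_classes,
                       if (has_test) test$X else NULL,
                       if (has_test) test$y else NULL)
  model$weights <- lapply(fit$weights, function(x) {
    if (is.matrix(x) && (nrow(x) == 1L)) as.numeric(x) else x
  })
  h <- fit$history
  model$history <- data.frame(epoch = seq_len(nrow(h)),
                              train_loss = h[, 1], train_acc = h[, 2],
                              test_loss = h[, 3], test_acc = h[, 4])
  model$trained <- TRUE
  model
}

# Softmax scores for a matrix of spectra, chunked to bound memory.
cnn_predict_raw <- function(w, cfg, X, chunk = 128L) {
  cnn_scores_cpp(X, w, cfg$relu_output, cfg$conv_kernel, cfg$pool_size,
                 chunk)
}

#' Predict mildew grades with a fitted CNN
#'
#' @param object a `cnn1d` object.
#' @param ds a [spectral_dataset()] with the training variable count.
#' @param type `"class"` for grade codes, `"prob"` for the softmax score
#'   matrix (rows sum to 1).
#' @param ... unused.
#' @return Integer grade vector or score matrix.
#' @export
predict.cnn1d <- function(object, ds, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(ds, "spectral_dataset")) ds$X else as.matrix(ds)
  if (ncol(X) != object$input_length)
    stop("dataset has ", ncol(X), " variables; model expects ",
         object$input_length)
  if (nrow(X) == 0) {
    return(if (type == "class") integer(0)
           else matrix(numeric(0), 0, object$cfg$n_classes))
  }
  S <- cnn_predict_raw(object$weights, object$cfg, X)
  if (type == "prob") S else max.col(S, ties.method = "first") - 1L
}

#' Activations of the 64-unit feature layer
#'
#' Returns, per sample, the ReLU activations of the fully connected
#' feature layer feeding the classifier head — the learned representation
#' visualised with t-SNE.
#'
#' @param model a fitted `cnn1d`.
#' @param ds a [spectral_dataset()].
#' @return Numeric matrix, `n_samples x dense_units`.
#' @export
extract_features <- function(model, ds) {
  if (!inherits(model, "cnn1d"))
    stop("feature extraction is defined for CNN models only")
  X <- if (inherits(ds, "spectral_dataset")) ds$X else as.matrix(ds)
  cfg <- model$cfg
  cnn_features_cpp(X, model$weights, cfg$relu_output, cfg$conv_kernel,
                   cfg$pool_size, 128L)
}

#' @export
print.cnn1d <- function(x, ...) {
  s <- x$sizes
  cat("<cnn1d> ", if (x$trained) "fitted" else "untrained",
      "; input ", s[["input"]], " variables\n", sep = "")
  cat("  conv(", x$cfg$conv_filters, "x", x$cfg$conv_kernel, ") -> ",
      s[["conv1"]], " -> pool -> ", s[["pool1"]], " -> conv -> ",
      s[["conv2"]], " -> pool -> ", s[["pool2"]], " -> flatten ",
      s[["flatten"]], " -> dense ", s[["dense"]], " -> ", s[["output"]],
      " (softmax)\n", sep = "")
  if (nrow(x$history))
    cat("  last epoch: train acc ",
        round(100 * utils::tail(x$history$train_acc, 1), 2), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.cnn1d <- function(object, ...) {
  print(object)
  np <- sum(vapply(object$weights, length, numeric(1)))
  cat("  parameters:", format(np, big.mark = ","), "\n")
  cat("  epochs:", object$cfg$epochs, " batch:", object$cfg$batch_size,
      " lr:", object$cfg$learning_rate,
      " dropout:", object$cfg$dropout_rate, "\n")
  invisible(object)
}

#' Plot CNN accuracy/loss curves
#'
#' @param x a fitted `cnn1d` with non-empty history.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cnn1d <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot")
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$test_acc), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "test"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$test_loss), type = "l",
                    lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "loss", ...)
  invisible(x)
}
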