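#' ANN configuration
#'
#' Single-hidden-layer sigmoid network regressed on the grade codes
#' 0/1/2, trained by full-batch gradient descent with momentum (0.9) and
#' an adaptive learning rate (grown 1.05x after an improving step, shrunk
#' 0.7x and the step rejected when the MSE worsens by more than 4% -- the
#' classic variable-learning-rate scheme of conventional neural-network
#' toolboxes): 100 sigmoid hidden units, initial learning rate 0.1, at
#' most 1000 iterations, stopping early when the MSE reaches the 0.001
#' target. The output unit is `2 * sigmoid`, spanning the grade range.
#' Predictions are judged with the deviation rule ([ann_decide()]):
#' correct when the raw output lies within 0.5 of the true code.
#'
#' @param hidden_units hidden layer width (100).
#' @param learning_rate gradient-descent step (0.1).
#' @param max_iterations iteration cap (1000).
#' @param target_error MSE stopping threshold (0.001).
#' @param decision_threshold deviation threshold of the decision rule (0.5).
#' @param seed integer seed for weight initialisation.
#' @return An `ann_config` list.
#' @export
ann_config <- function(hidden_units = 100L, learning_rate = 0.1,
                       max_iterations = 1000L, target_error = 0.001,
                       decision_threshold = 0.5, seed = 1L) {
  structure(list(hidden_units = as.integer(hidden_units),
                 learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 target_error = target_error,
                 decision_threshold = decision_threshold,
                 seed = as.integer(seed)),
            class = "ann_config")
}

#' SVM configuration (RBF kernel, penalty 0.8)
#'
#' @param penalty_c soft-margin penalty (0.8).
#' @param gamma RBF width; the default `NULL` uses the scale-adaptive
#'   policy `1 / (n_variables * var(X_train))`, which reduces to the
#'   classic `1/n_variables` on unit-variance features but stays
#'   calibrated when a pretreatment (e.g. the derivative) changes the
#'   feature scale.
#' @return An `svm_config` list.
#' @export
svm_config <- function(penalty_c = 0.8, gamma = NULL) {
  stopifnot(penalty_c > 0)
  structure(list(penalty_c = penalty_c, gamma = gamma),
            class = "svm_config")
}

#' KNN configuration (Euclidean, k = 3)
#'
#' @param n_neighbors neighbour count (3).
#' @return A `knn_config` list.
#' @export
knn_config <- function(n_neighbors = 3L) {
  stopifnot(n_neighbors >= 1)
  structure(list(n_neighbors = as.integer(n_neighbors)),
            class = "knn_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fit the comparator ANN
#'
#' @param train a [spectral_dataset()].
#' @param cfg an [ann_config()].
#' @return An object of class `ann_reg` (also `mildew_model`) with fields
#'   `weights`, `cfg`, `mse` (per-iteration trace) and `iterations`.
#' @export
fit_ann <- function(train, cfg = ann_config()) {
  X <- train$X; y <- as.numeric(train$y)
  n <- nrow(X); p <- ncol(X); h <- cfg$hidden_units
  if (n == 0) stop("empty training set")
  set.seed(cfg$seed)
  W1 <- matrix(stats::rnorm(p * h, 0, 1 / sqrt(p)), p, h); b1 <- rep(0, h)
  W2 <- matrix(stats::rnorm(h, 0, 1 / sqrt(h)), h, 1); b2 <- 0
  lr <- cfg$learning_rate
  mom <- 0.9
  vW1 <- W1 * 0; vb1 <- b1 * 0; vW2 <- W2 * 0; vb2 <- 0
  forward <- function(W1, b1, W2, b2) {
    H <- sigmoid(sweep(X %*% W1, 2, b1, "+"))
    out <- 2 * sigmoid(as.numeric(H %*% W2) + b2)
    list(H = H, out = out, mse = mean((out - y)^2))
  }
  fw <- forward(W1, b1, W2, b2)
  trace <- fw$mse
  if (!is.finite(fw$mse)) stop("divergent ANN training (non-finite MSE)")
  iter <- 0L
  while (fw$mse > cfg$target_error && iter < cfg$max_iterations) {
    iter <- iter + 1L
    err <- fw$out - y
    s <- fw$out / 2                      # d out / d z2 = 2 s (1 - s)
    dz2 <- matrix((2 / n) * err * 2 * s * (1 - s), ncol = 1)
    gW2 <- crossprod(fw$H, dz2); gb2 <- sum(dz2)
    dH <- (dz2 %*% t(W2)) * fw$H * (1 - fw$H)
    gW1 <- crossprod(X, dH); gb1 <- colSums(dH)
    vW1 <- mom * vW1 - lr * gW1; vb1 <- mom * vb1 - lr * gb1
    vW2 <- mom * vW2 - lr * gW2; vb2 <- mom * vb2 - lr * gb2
    cand <- forward(W1 + vW1, b1 + vb1, W2 + vW2, b2 + vb2)
    if (!is.finite(cand$mse)) stop("divergent ANN training (non-finite MSE)")
    if (cand$mse > 1.04 * fw$mse) {
      # reject the step, damp the rate, reset momentum
      lr <- lr * 0.7
      vW1 <- vW1 * 0; vb1 <- vb1 * 0; vW2 <- vW2 * 0; vb2 <- 0
    } else {
      W1 <- W1 + vW1; b1 <- b1 + vb1; W2 <- W2 + vW2; b2 <- b2 + vb2
      fw <- cand
      lr <- lr * 1.05
    }
    trace <- c(trace, fw$mse)
  }
  structure(list(weights = list(W1 = W1, b1 = b1, W2 = W2, b2 = b2),
                 cfg = cfg, mse = trace, iterations = iter),
            class = c("ann_reg", "mildew_model"))
}

ann_raw_output <- function(object, X) {
  w <- object$weights
  H <- sigmoid(sweep(X %*% w$W1, 2, w$b1, "+"))
  2 * sigmoid(as.numeric(H %*% w$W2) + w$b2)
}

#' Deviation-rule decision for the ANN's scalar output
#'
#' The scalar regression output is mapped to the nearest grade code
#' (rounded, clipped to 0..2); the prediction counts as correct only when
#' the raw output lies strictly within the deviation threshold (0.5) of
#' the true code.
#'
#' @param raw_output numeric vector of raw network outputs.
#' @param true_grade integer vector of true grade codes.
#' @param threshold deviation threshold (default 0.5).
#' @return A list with `label` (assigned codes) and `correct` (logical).
#' @export
ann_decide <- function(raw_output, true_grade, threshold = 0.5) {
  if (any(!is.finite(raw_output))) stop("non-finite ANN output")
  label <- pmin(pmax(round(raw_output), 0), 2)
  list(label = as.integer(label),
       correct = abs(raw_output - true_grade) < threshold)
}

#' @export
predict.ann_reg <- function(object, ds,
                            type = c("class", "raw"), ...) {
  type <- match.arg(type)
  X <- if (inherits(ds, "spectral_dataset")) ds$X else as.matrix(ds)
  if (nrow(X) == 0) return(if (type == "raw") numeric(0) else integer(0))
  raw <- ann_raw_output(object, X)
  if (type == "raw") raw
  else as.integer(pmin(pmax(round(raw), 0), 2))
}

#' @export
print.ann_reg <- function(x, ...) {
  cat("<ann_reg> ", x$cfg$hidden_units, " sigmoid hidden units; ",
      x$iterations, " iterations, final MSE ",
      format(utils::tail(x$mse, 1), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Fit the RBF-kernel SVM comparator
#'
#' Soft-margin support vector classifier with a radial basis kernel and
#' penalty 0.8, via libsvm. Fully deterministic given the training set.
#'
#' @param train a [spectral_dataset()].
#' @param cfg an [svm_config()].
#' @return An object of class `svm_rbf` (also `mildew_model`).
#' @export
fit_svm <- function(train, cfg = svm_config()) {
  if (length(unique(train$y)) < 2)
    stop("degenerate single-class training set")
  gamma <- if (is.null(cfg$gamma)) {
    1 / (ncol(train$X) * stats::var(as.vector(train$X)))
  } else cfg$gamma
  fit <- e1071::svm(x = train$X, y = factor(train$y, levels = GRADE_CODES),
                    kernel = "radial", cost = cfg$penalty_c, gamma = gamma,
                    scale = FALSE)
  structure(list(fit = fit, cfg = cfg), class = c("svm_rbf", "mildew_model"))
}

#' @export
predict.svm_rbf <- function(object, ds, ...) {
  X <- if (inherits(ds, "spectral_dataset")) ds$X else as.matrix(ds)
  if (nrow(X) == 0) return(integer(0))
  as.integer(as.character(predict(object$fit, X)))
}

#' @export
print.svm_rbf <- function(x, ...) {
  cat("<svm_rbf> RBF kernel, C =", x$cfg$penalty_c,
      ";", x$fit$tot.nSV, "support vectors\n")
  invisible(x)
}

#' Fit the KNN comparator
#'
#' Stores the training set; prediction is Euclidean k-nearest-neighbour
#' majority vote with deterministic tie-breaks (tied classes are resolved
#' by the nearest neighbour among them, then by the lowest grade code), so
#' repeated training and prediction are exactly reproducible.
#'
#' @param train a [spectral_dataset()].
#' @param cfg a [knn_config()].
#' @return An object of class `knn_model` (also `mildew_model`).
#' @export
fit_knn <- function(train, cfg = knn_config()) {
  if (nrow(train$X) < cfg$n_neighbors)
    stop("fewer training samples than neighbours")
  structure(list(X = train$X, y = train$y, cfg = cfg),
            class = c("knn_model", "mildew_model"))
}

#' @export
predict.knn_model <- function(object, ds, ...) {
  X <- if (inherits(ds, "spectral_dataset")) ds$X else as.matrix(ds)
  n <- nrow(X)
  if (n == 0) return(integer(0))
  k <- object$cfg$n_neighbors
  # squared Euclidean distances query x train
  d2 <- outer(rowSums(X^2), rep(1, nrow(object$X))) +
    outer(rep(1, n), rowSums(object$X^2)) - 2 * tcrossprod(X, object$X)
  out <- integer(n)
  for (i in seq_len(n)) {
    nb <- order(d2[i, ])[seq_len(k)]    # order() is a stable sort: ties -> lowest index
    votes <- table(factor(object$y[nb], levels = GRADE_CODES))
    top <- GRADE_CODES[votes == max(votes)]
    if (length(top) == 1L) { out[i] <- top; next }
    # tie: class of the nearest neighbour among the tied classes
    out[i] <- object$y[nb[which(object$y[nb] %in% top)[1]]]
  }
  out
}

#' @export
print.knn_model <- function(x, ...) {
  cat("<knn_model> k =", x$cfg$n_neighbors, "on",
      nrow(x$X), "stored samples\n")
  invisible(x)
}

#' Fit any of the four classifiers
#'
#' One front door over the CNN and the three comparators, all sharing the
#' `predict(model, dataset)` contract (grade codes out).
#'
#' @param kind `"cnn"`, `"ann"`, `"svm"` or `"knn"`.
#' @param train a [spectral_dataset()].
#' @param cfg the matching config object; `NULL` for defaults.
#' @param seed overrides the config seed for the stochastic models
#'   (CNN, ANN); ignored for SVM/KNN, which are deterministic.
#' @param ... passed to the specific fitting function (e.g. `test` for the
#'   CNN's monitoring set).
#' @return A fitted `mildew_model`.
#' @export
fit_model <- function(kind = c("cnn", "ann", "svm", "knn"), train,
                      cfg = NULL, seed = NULL, ...) {
  kind <- match.arg(kind)
  switch(kind,
    cnn = {
      if (is.null(cfg)) cfg <- cnn_config()
      if (!is.null(seed)) cfg$seed <- as.integer(seed)
      fit_cnn(train, cfg, ...)
    },
    ann = {
      if (is.null(cfg)) cfg <- ann_config()
      if (!is.null(seed)) cfg$seed <- as.integer(seed)
      fit_ann(train, cfg)
    },
    svm = fit_svm(train, if (is.null(cfg)) svm_config() else cfg),
    knn = fit_knn(train, if (is.null(cfg)) knn_config() else cfg))
}

#' Is a model kind deterministic across repeated fits?
#'
#' @param kind model kind string.
#' @return TRUE for SVM and KNN, FALSE for CNN and ANN.
#' @export
is_deterministic_model <- function(kind) kind %in% c("svm", "knn")
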