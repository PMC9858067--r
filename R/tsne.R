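#' t-SNE embedding of a feature matrix
#'
#' Exact (dense) t-distributed stochastic neighbour embedding: input
#' affinities from a per-point Gaussian kernel whose bandwidth is tuned by
#' bisection to the requested perplexity, symmetrised and exaggerated for
#' the first quarter of the optimisation; output affinities from the
#' Student-t kernel; gradient descent with momentum. All randomness (the
#' initial layout) comes from `seed`, so the map is reproducible.
#' Intended for the few hundred samples of this application; cost is
#' quadratic in the sample count.
#'
#' @param features numeric matrix (samples x features), >= 5 rows.
#' @param seed integer seed.
#' @param perplexity effective neighbour count (default 30, reduced
#'   automatically if the sample count is small).
#' @param n_iter gradient-descent iterations (default 500).
#' @param learning_rate step size (default 100).
#' @return Numeric matrix `n x 2` of map coordinates.
#' @export
tsne_map <- function(features, seed = 1L, perplexity = 30,
                     n_iter = 500L, learning_rate = 100) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 5) stop("t-SNE needs at least 5 samples")
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2

  # per-point bandwidths by bisection on entropy
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    d <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-d * beta)
      sp <- sum(p)
      if (sp == 0) p <- rep(1 / length(d), length(d)) else p <- p / sp
      H <- -sum(p * log(pmax(p, 1e-300)))
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, 0, 1e-4), n, 2)
  G <- matrix(0, n, 2)     # momentum buffer
  exag_until <- max(1L, n_iter %/% 4L)
  for (it in seq_len(n_iter)) {
    Pe <- if (it <= exag_until) P * 4 else P
    sumY <- rowSums(Y^2)
    num <- 1 / (1 + outer(sumY, sumY, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (Pe - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    momentum <- if (it <= 20) 0.5 else 0.8
    G <- momentum * G - learning_rate * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Scatter plot of a t-SNE map coloured by grade
#'
#' @param coords `n x 2` coordinate matrix from [tsne_map()].
#' @param y grade codes for colouring.
#' @param ... passed to [graphics::plot()].
#' @export
plot_tsne <- function(coords, y, ...) {
  cols <- c("#1b9e77", "#d95f02", "#7570b3")[y + 1L]
  graphics::plot(coords[, 1], coords[, 2], col = cols, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  graphics::legend("topright", GRADE_NAMES, col = c("#1b9e77", "#d95f02", "#7570b3"),
                   pch = 19, bty = "n")
  invisible(coords)
}
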