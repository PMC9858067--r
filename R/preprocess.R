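#' Preprocessing configuration
#'
#' Selects one of the three pretreatment arms compared in the pipeline:
#' `"np"` (no preprocessing beyond the Z-score), `"fd"` (Savitzky-Golay
#' first derivative) or `"snv"` (standard normal variate), with the
#' per-variable Z-score applied first in all arms.
#'
#' @param method `"np"`, `"fd"` or `"snv"`.
#' @param sg_window odd Savitzky-Golay window length (smoothing points);
#'   default 17.
#' @param sg_polyorder polynomial order of the local fit; default 2.
#' @param sg_deriv derivative order (1 for FD).
#' @param apply_zscore apply the per-variable Z-score first (default TRUE).
#' @param sg_scale divide the derivative by the grid spacing so it is in
#'   physical per-cm^-1 units (TRUE); the default FALSE keeps the
#'   derivative per grid step, which leaves standardised spectra on an
#'   O(1) scale that the fixed model hyperparameters (RBF gamma, network
#'   initialisation) are calibrated for. The two differ by the constant
#'   grid spacing only.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(method = c("np", "fd", "snv"),
                              sg_window = 17L, sg_polyorder = 2L,
                              sg_deriv = 1L, apply_zscore = TRUE,
                              sg_scale = FALSE) {
  method <- match.arg(method)
  sg_window <- as.integer(sg_window)
  if (sg_window %% 2L == 0L || sg_window <= sg_polyorder)
    stop("sg_window must be odd and greater than sg_polyorder")
  if (sg_deriv > sg_polyorder)
    stop("sg_deriv must not exceed sg_polyorder")
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = as.integer(sg_polyorder),
                 sg_deriv = as.integer(sg_deriv),
                 apply_zscore = isTRUE(apply_zscore),
                 sg_scale = isTRUE(sg_scale)),
            class = "preprocess_config")
}

#' Fit per-variable Z-score statistics
#'
#' Computes the per-variable mean and sample (n-1) standard deviation over
#' the training rows. Statistics are fitted on the training split only and
#' reused unchanged on the test split, so no test information leaks into
#' the standardisation.
#'
#' @param train a [spectral_dataset()] with at least 2 samples.
#' @return A `zscore_stats` list with `mean` and `sd` vectors.
#' @export
zscore_fit <- function(train) {
  if (nrow(train$X) < 2) stop("need >= 2 training samples to fit Z-score")
  m <- colMeans(train$X)
  s <- apply(train$X, 2, stats::sd)
  zero <- which(s == 0)
  if (length(zero))
    stop("zero-variance variable at column ", zero[1],
         " (wavenumber ", train$wavenumbers[zero[1]], " cm^-1)")
  structure(list(mean = m, sd = s), class = "zscore_stats")
}

#' Apply fitted Z-score statistics
#'
#' @param ds a [spectral_dataset()].
#' @param stats a [zscore_fit()] result with matching variable count.
#' @return The standardised dataset; grid and labels untouched.
#' @export
zscore_apply <- function(ds, stats) {
  if (length(stats$mean) != ncol(ds$X))
    stop("Z-score statistics have ", length(stats$mean),
         " variables, dataset has ", ncol(ds$X))
  out <- ds
  out$X <- sweep(sweep(ds$X, 2, stats$mean, "-"), 2, stats$sd, "/")
  out
}

#' Standard normal variate transform
#'
#' Centres each spectrum (row) by its own mean and scales by its own sample
#' standard deviation, removing multiplicative scatter and additive offsets
#' per spectrum. Affine-invariant: `a*s + b` (a > 0) maps to the same
#' output as `s`.
#'
#' @param ds a [spectral_dataset()] with >= 2 variables.
#' @return The row-standardised dataset (each row has mean 0, sample sd 1).
#' @export
snv <- function(ds) {
  if (ncol(ds$X) < 2) stop("SNV needs >= 2 variables per spectrum")
  m <- rowMeans(ds$X)
  s <- apply(ds$X, 1, stats::sd)
  zero <- which(s == 0)
  if (length(zero))
    stop("constant spectrum (zero row sd) for sample '",
         ds$sample_ids[zero[1]], "'")
  out <- ds
  out$X <- (ds$X - m) / s
  out
}

# Central Savitzky-Golay convolution kernel for (window, polyorder, deriv).
# Row (window+1)/2 of the signal::sgolay filter matrix is the interior
# filter; ts scales the derivative to per-unit-x.
sg_kernel <- function(window, polyorder, deriv, ts = 1) {
  F <- signal::sgolay(p = polyorder, n = window, m = deriv, ts = ts)
  as.numeric(F[(window + 1L) %/% 2L, ])
}

#' Savitzky-Golay first derivative
#'
#' Convolves each spectrum with the least-squares polynomial-smoothing
#' derivative kernel (default: 17 smoothing points, polynomial order 2,
#' first derivative). The derivative is expressed per unit wavenumber by
#' dividing by the grid spacing (disable with `sg_scale = FALSE` in the
#' config). Edges are handled by mirror padding so the output keeps the
#' input length and the grids of the two modalities stay aligned for
#' fusion. Exact for polynomials up to the configured order at interior
#' points.
#'
#' @param ds a [spectral_dataset()] on a uniformly spaced grid with at
#'   least `sg_window` variables.
#' @param cfg a [preprocess_config()].
#' @return The differentiated dataset, same dimensions.
#' @export
savgol_fd <- function(ds, cfg = preprocess_config("fd")) {
  p <- ncol(ds$X)
  w <- cfg$sg_window
  if (p < w) stop("spectrum has ", p, " variables; window is ", w)
  d <- diff(ds$wavenumbers)
  if (any(abs(abs(d) - abs(d[1])) / abs(d[1]) > 1e-6))
    stop("non-uniform wavenumber grid; Savitzky-Golay needs constant spacing")
  # kernel acts per index step; rescale so the derivative is w.r.t.
  # increasing wavenumber regardless of storage order
  scale <- if (cfg$sg_scale) 1 / d[1]^cfg$sg_deriv else sign(d[1])^cfg$sg_deriv
  k <- scale * sg_kernel(w, cfg$sg_polyorder, cfg$sg_deriv, ts = 1)
  h <- (w - 1L) %/% 2L
  idx <- c((h + 1L):2L, 1:p, (p - 1L):(p - h))  # mirror padding
  Xp <- ds$X[, idx, drop = FALSE]
  out <- ds
  # y[j] = sum_i k[i] * x[j - h + (i-1)] on the padded axis
  Y <- matrix(0, nrow(ds$X), p)
  for (i in seq_len(w)) {
    Y <- Y + k[i] * Xp[, (i - 1L) + 1:p, drop = FALSE]
  }
  out$X <- Y
  out
}

#' Apply a preprocessing arm
#'
#' Applies the per-variable Z-score (statistics fitted on the training
#' split) and then the configured method: `"np"` is the Z-score alone,
#' `"fd"` adds the Savitzky-Golay first derivative, `"snv"` the standard
#' normal variate. Preprocessing is applied per modality, before fusion.
#' Labels, sample ids and the grid are never altered.
#'
#' @param ds a [spectral_dataset()].
#' @param cfg a [preprocess_config()].
#' @param stats a [zscore_fit()] result (required when
#'   `cfg$apply_zscore`).
#' @return The preprocessed dataset.
#' @export
preprocess <- function(ds, cfg, stats = NULL) {
  out <- ds
  if (cfg$apply_zscore) {
    if (is.null(stats)) stop("Z-score enabled but no fitted statistics given")
    out <- zscore_apply(out, stats)
  }
  switch(cfg$method,
         np = out,
         fd = savgol_fd(out, cfg),
         snv = snv(out))
}
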