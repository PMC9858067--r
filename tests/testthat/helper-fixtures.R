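# Shared fixtures and independent oracles for the test suite.

# Small valid dataset on a short in-range NIRr grid.
tiny_dataset <- function(n = 4, p = 8, seed = 42, modality = "nirr") {
  set.seed(seed)
  base_wn <- if (modality == "nirt") 5793 else 3996
  spectral_dataset(matrix(abs(rnorm(n * p)), n, p),
                   rev(base_wn + 16 * (seq_len(p) - 1)),
                   y = rep(0:2, length.out = n),
                   modality = modality)
}

# Compact synthetic config: short grids, three well-separated bands, low
# noise; keeps model tests fast while exercising the full pipeline.
tiny_config <- function(n0 = 24, n1 = 18, n2 = 24, seed = 7,
                        noise_sd = 0.01, baseline_offset_sd = 0.02,
                        scatter_sd = 0.05) {
  nirr_grid <- rev(3996 + 16 * (0:39))   # 40 vars
  nirt_grid <- rev(5793 + 16 * (0:29))   # 30 vars
  bands <- list(
    band_spec(4300, 60, 0.3, modality = "nirr"),
    band_spec(4180, 50, 0.15, c(0, 0.03, 0.10), modality = "nirr"),
    band_spec(6000, 60, 0.2, c(0, 0.10, 0.12), modality = "nirt"))
  profiles <- lapply(0:2, function(g)
    class_profile(g, c(n0, n1, n2)[g + 1],
                  baseline_offset_sd = baseline_offset_sd,
                  baseline_slope_sd = 0.01,
                  scatter_sd = scatter_sd, noise_sd = noise_sd,
                  side_jitter_sd = 0.005))
  synthetic_config(nirr_grid, nirt_grid, bands, profiles, seed = seed)
}

# Noise-free variant: deterministic band sums only.
noise_free_config <- function(...) {
  cfg <- tiny_config(...)
  for (i in 1:3) {
    cfg$profiles[[i]]$baseline_offset_sd <- 0
    cfg$profiles[[i]]$baseline_slope_sd <- 0
    cfg$profiles[[i]]$scatter_sd <- 0
    cfg$profiles[[i]]$noise_sd <- 0
    cfg$profiles[[i]]$side_jitter_sd <- 0
  }
  cfg
}

# Independent Savitzky-Golay derivative filter: explicit least-squares
# polynomial fit over the window, derivative coefficient at the centre.
ls_sg_derivative_filter <- function(window, polyorder, deriv = 1) {
  h <- (window - 1) / 2
  x <- (-h):h
  V <- outer(x, 0:polyorder, "^")
  pinv <- solve(t(V) %*% V, t(V))
  factorial(deriv) * pinv[deriv + 1, ]
}

# Independent brute-force greedy max-min Kennard-Stone oracle.
ks_oracle <- function(X, n_select) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- -Inf; pair <- c(1L, 2L)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (d(i, j) > best) { best <- d(i, j); pair <- c(i, j) }
  }
  sel <- pair
  while (length(sel) < n_select) {
    cand <- setdiff(seq_len(n), sel)
    mind <- vapply(cand, function(c1)
      min(vapply(sel, function(s1) d(c1, s1), numeric(1))), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  as.integer(sel)
}
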