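test_that("Z-score statistics use the sample sd and flag degenerate variables", {
  ds <- tiny_dataset(n = 2, p = 4)
  ds$X <- matrix(c(1, 3, 1, 3, 0, 4, 2, 6), 2, 4)
  st <- zscore_fit(ds)
  expect_equal(st$mean, c(2, 2, 2, 4))
  expect_equal(st$sd[1], sqrt(2))

  const <- ds
  const$X[, 3] <- 5
  expect_error(zscore_fit(const), "zero-variance variable at column 3")
  expect_error(zscore_fit(tiny_dataset(n = 1)), ">= 2 training samples")
})

test_that("Z-score application standardises the fitted set and never refits", {
  d <- generate_dataset(tiny_config())
  st <- zscore_fit(d$nirr)
  z <- zscore_apply(d$nirr, st)
  expect_lt(max(abs(colMeans(z$X))), 1e-12)
  expect_lt(max(abs(apply(z$X, 2, sd) - 1)), 1e-12)
  expect_identical(z$y, d$nirr$y)
  expect_identical(z$wavenumbers, d$nirr$wavenumbers)

  ident <- zscore_apply(d$nirr, structure(
    list(mean = rep(0, ncol(d$nirr$X)), sd = rep(1, ncol(d$nirr$X))),
    class = "zscore_stats"))
  expect_equal(ident$X, d$nirr$X)

  shifted <- d$nirr
  shifted$X <- shifted$X + 1          # translated "test set", same stats
  expect_equal(zscore_apply(shifted, st)$X, z$X + sweep(matrix(1, nrow(z$X), ncol(z$X)), 2, st$sd, "/"))
  expect_error(zscore_apply(subset_samples(d$nirt, 1:3), st), "variables")
})

test_that("SNV standardises rows, is affine-invariant and idempotent", {
  ds <- tiny_dataset(n = 1, p = 3)
  ds$X <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(as.numeric(snv(ds)$X), c(-1, 0, 1))

  d <- snv(generate_dataset(tiny_config())$nirr)
  expect_lt(max(abs(rowMeans(d$X))), 1e-10)
  expect_lt(max(abs(apply(d$X, 1, sd) - 1)), 1e-10)
  expect_equal(snv(d)$X, d$X, tolerance = 1e-12)

  const <- ds
  const$X[1, ] <- 7
  expect_error(snv(const), "constant spectrum .* 's1'")
})

test_that("Savitzky-Golay derivative is exact on polynomials at interior points", {
  p <- 41
  grid <- rev(3996 + 16 * (0:(p - 1)))
  w <- sort(grid)
  cfg <- preprocess_config("fd", apply_zscore = FALSE, sg_scale = TRUE)
  h <- (cfg$sg_window - 1) / 2
  interior <- (h + 1):(p - h)

  mk <- function(f) spectral_dataset(rbind(f(grid)), grid, 0L, modality = "nirr")

  out <- savgol_fd(mk(function(x) rep(5, length(x))), cfg)
  expect_lt(max(abs(out$X)), 1e-9)                       # constant -> 0

  out <- savgol_fd(mk(function(x) 2 * x + 1), cfg)
  expect_lt(max(abs(out$X[1, interior] - 2)), 1e-9)      # linear -> slope

  quad <- function(x) 0.003 * x^2 - 4 * x + 10
  dquad <- function(x) 0.006 * x - 4
  out <- savgol_fd(mk(quad), cfg)
  expect_lt(max(abs(out$X[1, interior] - dquad(grid[interior]))), 1e-9)
})

test_that("the convolution kernel equals the least-squares local-fit oracle", {
  k_pkg <- mildewfusion:::sg_kernel(17, 2, 1, ts = 1)
  k_ls <- ls_sg_derivative_filter(17, 2, 1)
  expect_equal(as.numeric(k_pkg), as.numeric(k_ls), tolerance = 1e-10)
  # and for another admissible configuration
  expect_equal(as.numeric(mildewfusion:::sg_kernel(11, 3, 1, ts = 1)),
               as.numeric(ls_sg_derivative_filter(11, 3, 1)),
               tolerance = 1e-10)
})

test_that("savgol_fd is linear and rejects bad inputs", {
  d <- generate_dataset(tiny_config())$nirr
  a <- subset_samples(d, 1:3); b <- subset_samples(d, 4:6)
  cfg <- preprocess_config("fd", apply_zscore = FALSE)
  lin <- a; lin$X <- 2 * a$X + 3 * b$X
  expect_equal(savgol_fd(lin, cfg)$X,
               2 * savgol_fd(a, cfg)$X + 3 * savgol_fd(b, cfg)$X,
               tolerance = 1e-10)

  short <- subset_samples(d, 1)
  short$X <- short$X[, 1:10, drop = FALSE]
  short$wavenumbers <- short$wavenumbers[1:10]
  expect_error(savgol_fd(short, cfg), "window")
  expect_error(preprocess_config("fd", sg_window = 16), "odd")
  expect_error(preprocess_config("fd", sg_polyorder = 1, sg_deriv = 2),
               "sg_deriv")
})

test_that("preprocess composes Z-score with the chosen method and preserves metadata", {
  d <- generate_dataset(tiny_config())$nirr
  st <- zscore_fit(d)
  np <- preprocess(d, preprocess_config("np"), st)
  # NP on already-standardised data is the identity
  st_id <- structure(list(mean = rep(0, ncol(np$X)), sd = rep(1, ncol(np$X))),
                     class = "zscore_stats")
  expect_equal(preprocess(np, preprocess_config("np"), st_id)$X, np$X)

  sn <- preprocess(d, preprocess_config("snv"), st)
  expect_lt(max(abs(rowMeans(sn$X))), 1e-10)
  expect_lt(max(abs(apply(sn$X, 1, sd) - 1)), 1e-10)

  fd <- preprocess(d, preprocess_config("fd"), st)
  expect_identical(fd$y, d$y)
  expect_identical(fd$sample_ids, d$sample_ids)
  expect_identical(fd$wavenumbers, d$wavenumbers)
  expect_error(preprocess(d, preprocess_config("fd")), "no fitted statistics")
})

test_that("FD sharpens class separation relative to NP under heavy baseline drift", {
  cfg <- tiny_config(n0 = 30, n1 = 30, n2 = 30,
                     baseline_offset_sd = 0.3, noise_sd = 0.002,
                     scatter_sd = 0.01)
  d <- generate_dataset(cfg)$nirr
  st <- zscore_fit(d)
  sep <- function(ds) {
    centroids <- lapply(0:2, function(g) colMeans(ds$X[ds$y == g, , drop = FALSE]))
    between <- mean(c(
      sqrt(sum((centroids[[1]] - centroids[[2]])^2)),
      sqrt(sum((centroids[[1]] - centroids[[3]])^2)),
      sqrt(sum((centroids[[2]] - centroids[[3]])^2))))
    within <- mean(vapply(0:2, function(g) {
      rows <- which(ds$y == g)
      mean(sqrt(rowSums(sweep(ds$X[rows, , drop = FALSE], 2,
                              centroids[[g + 1]])^2)))
    }, numeric(1)))
    between / within
  }
  np <- preprocess(d, preprocess_config("np"), st)
  fd <- preprocess(d, preprocess_config("fd"), st)
  expect_gt(sep(fd), sep(np))
})
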