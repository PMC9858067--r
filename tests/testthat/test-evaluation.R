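test_that("prediction accuracy is the percent-correct formula", {
  expect_equal(prediction_accuracy(rep(0:2, c(50, 25, 25)),
                                   c(rep(0, 47), rep(1, 28), rep(2, 22),
                                     rep(0, 3))), 94)
  expect_equal(prediction_accuracy(0:2, 0:2), 100)
  expect_error(prediction_accuracy(integer(0), integer(0)), "empty")

  # exhaustive small-case check against a brute-force count
  y <- c(0L, 1L, 2L)
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  for (p in perms) {
    yp <- y[p]
    expect_equal(prediction_accuracy(y, yp), 100 * sum(y == yp) / 3)
  }
})

test_that("weighted F1 matches a hand computation and its conventions", {
  expect_equal(weighted_f1(rep(0:2, 4), rep(0:2, 4)), 100)

  # two samples, class 1 predicted entirely as class 2:
  # class-0 F1 = 1 (1 sample), class-1 F1 = 0, class-2 absent (weight 0)
  # weighted = (1*1 + 1*0) / 2 = 0.5
  expect_equal(weighted_f1(c(0L, 1L), c(0L, 2L)), 50)

  # P + R = 0 for a class contributes zero
  expect_equal(weighted_f1(c(1L, 1L), c(0L, 2L)), 0)

  # equals PA whenever the confusion matrix is diagonal
  y <- rep(0:2, c(7, 3, 5))
  expect_equal(weighted_f1(y, y), prediction_accuracy(y, y))
})

test_that("confusion matrices count, normalise to row percent, and error on empty rows", {
  grade_names <- c("normal", "slightly moldy", "seriously moldy")
  y <- rep(0:2, c(10, 10, 10))
  cm <- confusion_counts(y, y)
  expect_equal(diag(cm), setNames(rep(10L, 3), grade_names))
  expect_equal(diag(confusion_percent(cm)), setNames(rep(100, 3), grade_names))

  m <- matrix(c(5, 3, 2, 0, 10, 0, 0, 0, 10), 3, 3, byrow = TRUE)
  pct <- confusion_percent(m)
  expect_equal(pct[1, ], c(50, 30, 20))
  expect_equal(unname(rowSums(pct)), rep(100, 3))
  expect_error(confusion_percent(diag(c(1, 0, 1))), "empty")
})

test_that("PA equals trace/total of the confusion counts on generated runs", {
  set.seed(8)
  for (i in 1:20) {
    y <- sample(0:2, 40, replace = TRUE)
    yp <- sample(0:2, 40, replace = TRUE)
    cm <- confusion_counts(y, yp)
    expect_equal(prediction_accuracy(y, yp), 100 * sum(diag(cm)) / sum(cm))
  }
})

test_that("the repeat protocol aggregates means, SDs and mean confusion matrices", {
  d <- generate_dataset(tiny_config())
  sp <- make_split(d)
  arm <- prepare_arm(d, sp, "fused", "fd")

  rk <- repeat_protocol("knn", arm$train, arm$test, n_repeats = 8)
  expect_equal(unname(rk$sd), rep(0, 4))              # deterministic model
  expect_length(rk$runs, 8)
  expect_equal(unname(rowSums(rk$confusion_test_pct)), rep(100, 3),
               tolerance = 1e-2)
  expect_equal(rk$mean[["pa_test"]], rk$runs[[1]]$pa_test)

  r1 <- repeat_protocol("knn", arm$train, arm$test, n_repeats = 1)
  expect_false(r1$sd_defined)
  expect_equal(unname(r1$sd), rep(0, 4))

  rc <- repeat_protocol("cnn", arm$train, arm$test,
                        cfg = cnn_config(epochs = 3), n_repeats = 2,
                        base_seed = 5)
  expect_equal(vapply(rc$runs, function(r) r$seed, numeric(1)), c(5, 6))
  expect_equal(rc$mean[["pa_test"]],
               mean(vapply(rc$runs, function(r) r$pa_test, numeric(1))))
  # SD uses the sample convention
  expect_equal(rc$sd[["pa_test"]],
               sd(vapply(rc$runs, function(r) r$pa_test, numeric(1))))
})

test_that("per-grade accuracy is the mean row-percent diagonal and equals per-class PA", {
  d <- generate_dataset(tiny_config())
  sp <- make_split(d)
  arm <- prepare_arm(d, sp, "fused", "fd")
  rk <- repeat_protocol("knn", arm$train, arm$test, n_repeats = 2)
  pg <- per_grade_accuracy(rk)
  expect_length(pg, 3)
  yp <- predict(rk$model, arm$test)
  for (g in 0:2) {
    rows <- arm$test$y == g
    expect_equal(unname(pg[g + 1]),
                 prediction_accuracy(arm$test$y[rows], yp[rows]))
  }
  perfect <- rk
  perfect$confusion_test_pct <- diag(c(100, 100, 100))
  expect_equal(unname(per_grade_accuracy(perfect)), c(100, 100, 100))
})

test_that("t-SNE maps are 2-D, seed-reproducible and separate far clusters", {
  set.seed(10)
  X <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 20), 30),
             matrix(rnorm(60, -20), 30))
  y <- rep(0:2, each = 30)
  co <- tsne_map(X, seed = 3, n_iter = 300)
  expect_equal(dim(co), c(90L, 2L))
  expect_identical(tsne_map(X, seed = 3, n_iter = 300), co)
  expect_false(identical(tsne_map(X, seed = 4, n_iter = 300), co))
  sil <- cluster::silhouette(y + 1, dist(co))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(tsne_map(X[1:3, ]), "at least 5")
})

test_that("accuracy/loss curves serialise the training history", {
  d <- generate_dataset(tiny_config())
  sp <- make_split(d)
  arm <- prepare_arm(d, sp, "fused", "fd")
  m <- fit_cnn(arm$train, cnn_config(epochs = 4, seed = 1), test = arm$test)
  path <- withr::local_tempfile(fileext = ".csv")
  h <- accuracy_loss_curves(m, path)
  expect_equal(nrow(h), 4)
  expect_true(all(is.finite(h$test_acc)))
  expect_equal(nrow(utils::read.csv(path)), 4)

  m0 <- fit_cnn(arm$train, cnn_config(epochs = 0, seed = 1))
  h0 <- accuracy_loss_curves(m0, path)
  expect_equal(nrow(h0), 0)
  expect_equal(nrow(utils::read.csv(path)), 0)       # header-only CSV
  expect_error(accuracy_loss_curves(fit_knn(arm$train)), "cnn1d")
})

test_that("training loss decreases to convergence on the separable noise-free fixture", {
  d <- generate_dataset(noise_free_config(n0 = 12, n1 = 12, n2 = 12))
  f <- fuse(d$nirr, d$nirt)
  set.seed(2)
  f$X <- f$X + matrix(rnorm(length(f$X), 0, 1e-4), nrow(f$X))
  z <- zscore_apply(f, zscore_fit(f))
  m <- fit_cnn(z, cnn_config(epochs = 15, seed = 1, dropout_rate = 0))
  h <- m$history$train_loss
  expect_lt(tail(h, 1), h[1])
  expect_lt(tail(h, 1), 0.05)
})
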