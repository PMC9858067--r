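# Shared small fused arm for model tests: ~70 variables, 66 samples.
local_arm <- local({
  d <- generate_dataset(tiny_config())
  sp <- make_split(d)
  prepare_arm(d, sp, "fused", "fd")
})

test_that("CNN layer arithmetic matches the closed form, including failures", {
  s <- cnn_layer_sizes(639)
  expect_identical(unname(s), c(639L, 637L, 212L, 210L, 70L, 4480L, 64L, 3L))
  # closed form for any admissible length: conv L-2, pool floor(L/3)
  for (L in c(100, 263, 376, 500)) {
    s <- cnn_layer_sizes(L)
    expect_equal(s[["conv1"]], L - 2L)
    expect_equal(s[["pool1"]], (L - 2L) %/% 3L)
    expect_equal(s[["conv2"]], s[["pool1"]] - 2L)
    expect_equal(s[["pool2"]], s[["conv2"]] %/% 3L)
    expect_equal(s[["flatten"]], s[["pool2"]] * 64L)
  }
  expect_error(cnn_layer_sizes(10), "second convolution")
  expect_error(cnn_layer_sizes(2), "kernel")
})

test_that("softmax scores are a probability simplex and argmax gives the label", {
  m <- fit_cnn(local_arm$train, cnn_config(epochs = 3, seed = 1))
  S <- predict(m, local_arm$test, type = "prob")
  expect_equal(rowSums(S), rep(1, nrow(S)), tolerance = 1e-6)
  expect_true(all(S >= 0))
  expect_identical(predict(m, local_arm$test),
                   max.col(S, ties.method = "first") - 1L)
  # the literal architecture variant (pre-softmax ReLU) is also a simplex
  m2 <- fit_cnn(local_arm$train, cnn_config(epochs = 2, seed = 1,
                                            relu_output = TRUE))
  S2 <- predict(m2, local_arm$test, type = "prob")
  expect_equal(rowSums(S2), rep(1, nrow(S2)), tolerance = 1e-6)
})

test_that("CNN training is reproducible from the seed, and zero epochs predict from init", {
  cfg <- cnn_config(epochs = 4, seed = 7)
  m1 <- fit_cnn(local_arm$train, cfg)
  m2 <- fit_cnn(local_arm$train, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$history, m2$history)
  m3 <- fit_cnn(local_arm$train, cnn_config(epochs = 4, seed = 8))
  expect_false(identical(m1$weights, m3$weights))

  m0 <- fit_cnn(local_arm$train, cnn_config(epochs = 0, seed = 7))
  expect_equal(nrow(m0$history), 0L)
  expect_false(m0$trained)
  expect_length(predict(m0, local_arm$test), nrow(local_arm$test$X))
})

test_that("the CNN fits separable noise-free data to 100% training accuracy", {
  d <- generate_dataset(noise_free_config(n0 = 12, n1 = 12, n2 = 12))
  f <- fuse(d$nirr, d$nirt)
  # tiny constant jitter so Z-score is defined, classes stay separated
  set.seed(2)
  f$X <- f$X + matrix(rnorm(length(f$X), 0, 1e-4), nrow(f$X))
  st <- zscore_fit(f)
  z <- zscore_apply(f, st)
  m <- fit_cnn(z, cnn_config(epochs = 20, seed = 1, dropout_rate = 0))
  expect_equal(prediction_accuracy(z$y, predict(m, z)), 100)
})

test_that("empty and mismatched prediction inputs are handled", {
  m <- fit_cnn(local_arm$train, cnn_config(epochs = 2, seed = 1))
  empty <- subset_samples(local_arm$test, integer(0))
  expect_identical(predict(m, empty), integer(0))
  expect_error(predict(m, local_arm$test$X[, 1:10]), "variables")
})

test_that("ann_decide applies the strict 0.5 deviation rule with clipping", {
  expect_true(ann_decide(1.3, 1)$correct)
  expect_identical(ann_decide(1.3, 1)$label, 1L)
  expect_false(ann_decide(1.5, 1)$correct)         # boundary is strict
  r <- ann_decide(2.7, 2)
  expect_false(r$correct)
  expect_identical(r$label, 2L)                    # clipped to the grade range
  expect_error(ann_decide(NaN, 1), "non-finite")
})

test_that("the ANN regresses grade codes: stopping rule, determinism, toy fit", {
  # target_error at or above the initial MSE stops before any update
  m0 <- fit_ann(local_arm$train, ann_config(target_error = 10, seed = 1))
  expect_identical(m0$iterations, 0L)

  m1 <- fit_ann(local_arm$train, ann_config(max_iterations = 30, seed = 2))
  m2 <- fit_ann(local_arm$train, ann_config(max_iterations = 30, seed = 2))
  expect_identical(m1$weights, m2$weights)

  # one-feature two-class toy problem reaches the 0.001 MSE target
  toy <- spectral_dataset(matrix(rep(c(-1, 1), each = 10) , ncol = 1),
                          5000, rep(c(0L, 1L), each = 10),
                          modality = "fused")
  mt <- fit_ann(toy, ann_config(seed = 3))
  expect_lte(tail(mt$mse, 1), 0.001)
  expect_identical(predict(mt, toy), toy$y)
})

test_that("SVM separates Gaussian blobs and is deterministic across refits", {
  set.seed(4)
  X <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 6), 20))
  blob <- spectral_dataset(abs(X), c(5016, 5000), rep(c(0L, 2L), each = 20),
                           modality = "nirr")
  sv <- fit_svm(blob)
  expect_equal(prediction_accuracy(blob$y, predict(sv, blob)), 100)
  expect_identical(predict(fit_svm(blob), blob), predict(sv, blob))

  one_class <- blob
  one_class$y <- rep(0L, 40)
  expect_error(fit_svm(one_class), "single-class")
})

test_that("KNN majority vote and deterministic tie-breaking", {
  train <- spectral_dataset(matrix(c(0, 0.1, 5, 0, 0.1, 5), 3, 2),
                            c(5016, 5000), c(0L, 0L, 2L),
                            modality = "nirr")
  kn <- fit_knn(train, knn_config(3))
  # neighbours labelled {0, 0, 2} -> majority 0
  expect_identical(predict(kn, matrix(c(0.05, 0.05), 1, 2)), 0L)

  kn1 <- fit_knn(train, knn_config(1))
  expect_identical(predict(kn1, train), train$y)     # own label at k = 1

  # 1-1 vote tie at k = 2: resolved by the nearer neighbour's class
  tie_train <- spectral_dataset(matrix(c(0, 1, 0, 1), 2, 2), c(5016, 5000),
                                c(2L, 1L), modality = "nirr")
  kn2 <- fit_knn(tie_train, knn_config(2))
  expect_identical(predict(kn2, matrix(c(0.1, 0.1), 1, 2)), 2L)
  expect_identical(predict(fit_knn(tie_train, knn_config(2)),
                           matrix(c(0.1, 0.1), 1, 2)), 2L)
})

test_that("fit_model dispatches all four kinds under one predict contract", {
  for (kind in c("cnn", "ann", "svm", "knn")) {
    cfg <- switch(kind, cnn = cnn_config(epochs = 2, seed = 1),
                  ann = ann_config(max_iterations = 20, seed = 1), NULL)
    m <- fit_model(kind, local_arm$train, cfg = cfg)
    pred <- predict(m, local_arm$test)
    expect_length(pred, nrow(local_arm$test$X))
    expect_true(all(pred %in% 0:2))
  }
  expect_true(is_deterministic_model("svm"))
  expect_true(is_deterministic_model("knn"))
  expect_false(is_deterministic_model("cnn"))
})

test_that("extracted features are the 64-unit dense activations, deterministic", {
  m <- fit_cnn(local_arm$train, cnn_config(epochs = 3, seed = 1))
  f1 <- extract_features(m, local_arm$test)
  expect_equal(dim(f1), c(nrow(local_arm$test$X), 64L))
  expect_identical(f1, extract_features(m, local_arm$test))
  expect_true(all(f1 >= 0))                         # ReLU layer
  expect_error(extract_features(fit_knn(local_arm$train), local_arm$test),
               "CNN")
  # trained features separate the classes at least at the centroid level
  cent <- lapply(0:2, function(g) colMeans(f1[local_arm$test$y == g, , drop = FALSE]))
  expect_gt(sqrt(sum((cent[[1]] - cent[[3]])^2)), 0)
})
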