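#' Prediction accuracy (percent)
#'
#' `PA = 100 * Nc / N`, the percentage of samples whose predicted grade
#' equals the true grade.
#'
#' @param y_true,y_pred equal-length grade vectors, nonempty.
#' @return Percent correct.
#' @export
prediction_accuracy <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  100 * mean(y_true == y_pred)
}

#' Support-weighted F1 score (percent)
#'
#' Per-class F1 = 2PR/(P+R) with precision P and recall R, combined as the
#' support-weighted mean over the three grades and expressed as percent.
#' A class with P + R = 0 (never predicted and never recovered)
#' contributes F1 = 0; classes absent from `y_true` carry zero weight.
#'
#' @param y_true,y_pred equal-length grade vectors, nonempty.
#' @return Weighted F1 in percent.
#' @export
weighted_f1 <- function(y_true, y_pred) {
  if (length(y_true) == 0) stop("empty input")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  f1 <- w <- numeric(length(GRADE_CODES))
  for (i in seq_along(GRADE_CODES)) {
    g <- GRADE_CODES[i]
    tp <- sum(y_true == g & y_pred == g)
    fp <- sum(y_true != g & y_pred == g)
    fn <- sum(y_true == g & y_pred != g)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[i] <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    w[i] <- sum(y_true == g)
  }
  100 * sum(f1 * w) / sum(w)
}

#' 3x3 confusion count matrix
#'
#' Rows are true grades, columns predicted grades.
#'
#' @param y_true,y_pred grade vectors.
#' @return Integer 3x3 matrix with grade-name dimnames.
#' @export
confusion_counts <- function(y_true, y_pred) {
  m <- table(factor(y_true, levels = GRADE_CODES),
             factor(y_pred, levels = GRADE_CODES))
  m <- matrix(as.integer(m), 3, 3,
              dimnames = list(true = GRADE_NAMES, predicted = GRADE_NAMES))
  m
}

#' Row-percent confusion matrix
#'
#' Divides each row (true grade) by its row sum and scales to percent, so
#' the diagonal holds the per-grade accuracies and every row sums to 100.
#'
#' @param counts 3x3 count matrix with positive row sums.
#' @return 3x3 percent matrix.
#' @export
confusion_percent <- function(counts) {
  rs <- rowSums(counts)
  if (any(rs == 0)) stop("empty confusion-matrix row (no samples of grade ",
                         GRADE_CODES[which(rs == 0)[1]], ")")
  100 * counts / rs
}

run_result <- function(seed, y_true_train, y_pred_train,
                       y_true_test, y_pred_test) {
  list(seed = seed,
       pa_train = prediction_accuracy(y_true_train, y_pred_train),
       pa_test = prediction_accuracy(y_true_test, y_pred_test),
       f1_train = weighted_f1(y_true_train, y_pred_train),
       f1_test = weighted_f1(y_true_test, y_pred_test),
       confusion_train = confusion_counts(y_true_train, y_pred_train),
       confusion_test = confusion_counts(y_true_test, y_pred_test))
}

#' Repeated-training evaluation protocol
#'
#' Trains the configured model once per seed (`base_seed`, `base_seed + 1`,
#' ..., n_repeats seeds) on a fixed train/test partition — the
#' Kennard-Stone split is deterministic, so the repeats vary only the
#' training randomness — and aggregates the mean and sample (n-1) SD of PA
#' and weighted F1 on both sets, plus mean confusion matrices (counts are
#' averaged element-wise across repeats, then converted to row percent).
#' For the deterministic models (SVM, KNN) a single fit is reused and the
#' SD is exactly 0.
#'
#' @param kind model kind (`"cnn"`, `"ann"`, `"svm"`, `"knn"`).
#' @param train,test [spectral_dataset()]s.
#' @param cfg model config (`NULL` for defaults).
#' @param n_repeats number of repeats (default 8).
#' @param base_seed first seed.
#' @return An `evaluation_report` list: `runs`, `mean`/`sd` named vectors
#'   (`pa_train`, `pa_test`, `f1_train`, `f1_test`), mean confusion count
#'   and percent matrices, `per_grade` accuracies, and metadata.
#' @export
repeat_protocol <- function(kind, train, test, cfg = NULL,
                            n_repeats = 8L, base_seed = 1L) {
  deterministic <- is_deterministic_model(kind)
  runs <- vector("list", n_repeats)
  model <- NULL
  last_model <- NULL
  for (r in seq_len(n_repeats)) {
    seed <- base_seed + r - 1L
    if (is.null(model) || !deterministic) {
      model <- fit_model(kind, train, cfg = cfg, seed = seed)
    }
    runs[[r]] <- run_result(seed,
                            train$y, predict(model, train),
                            test$y, predict(model, test))
    last_model <- model
  }
  metric <- function(nm) vapply(runs, function(r) r[[nm]], numeric(1))
  nms <- c("pa_train", "pa_test", "f1_train", "f1_test")
  means <- vapply(nms, function(nm) mean(metric(nm)), numeric(1))
  sds <- if (n_repeats > 1) {
    if (deterministic) vapply(nms, function(nm) 0, numeric(1))
    else vapply(nms, function(nm) stats::sd(metric(nm)), numeric(1))
  } else {
    vapply(nms, function(nm) 0, numeric(1))   # SD undefined for one run
  }
  mean_counts <- function(field) {
    Reduce(`+`, lapply(runs, function(r) r[[field]])) / n_repeats
  }
  cc_train <- mean_counts("confusion_train")
  cc_test <- mean_counts("confusion_test")
  structure(list(kind = kind, n_repeats = n_repeats, base_seed = base_seed,
                 sd_defined = n_repeats > 1,
                 runs = runs, mean = means, sd = sds,
                 confusion_train = cc_train, confusion_test = cc_test,
                 confusion_train_pct = confusion_percent(cc_train),
                 confusion_test_pct = confusion_percent(cc_test),
                 model = last_model),
            class = "evaluation_report")
}

#' Per-grade prediction accuracy
#'
#' Diagonal of the mean row-percent confusion matrix: the percentage of
#' samples of each true grade that were predicted as that grade.
#'
#' @param report an [repeat_protocol()] result.
#' @param set `"test"` or `"train"`.
#' @return Named numeric length-3 vector of percents.
#' @export
per_grade_accuracy <- function(report, set = c("test", "train")) {
  set <- match.arg(set)
  m <- if (set == "test") report$confusion_test_pct
       else report$confusion_train_pct
  stats::setNames(diag(m), GRADE_NAMES)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", toupper(x$kind), ", ", x$n_repeats,
      " repeat(s)\n", sep = "")
  f <- function(nm) sprintf("%.2f +/- %.2f", x$mean[[nm]], x$sd[[nm]])
  cat("  train: PA ", f("pa_train"), "%, F1 ", f("f1_train"), "%\n", sep = "")
  cat("  test:  PA ", f("pa_test"), "%, F1 ", f("f1_test"), "%\n", sep = "")
  pg <- per_grade_accuracy(x)
  cat("  per-grade test accuracy: ",
      paste(sprintf("%s %.1f%%", names(pg), pg), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Training-history table of accuracy/loss curves
#'
#' @param model a fitted `cnn1d`.
#' @param path optional CSV path; when given the table is also written.
#' @return The history data frame (`epoch`, `train_loss`, `train_acc`,
#'   `test_loss`, `test_acc`).
#' @export
accuracy_loss_curves <- function(model, path = NULL) {
  if (!inherits(model, "cnn1d")) stop("training history requires a cnn1d")
  h <- model$history
  if (!is.null(path))
    utils::write.csv(h, path, row.names = FALSE)
  h
}
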