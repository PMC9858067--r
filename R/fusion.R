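#' Fuse the two modalities into one block-concatenated dataset
#'
#' Column-wise concatenation `[X_nirr | X_nirt]` with the NIRr block first,
#' matching the conventional plotting order in which the reflectance
#' fingerprint region is discussed first. The boundary between the two
#' blocks (the "splicing site") is recorded as `splice`, the 1-based index
#' of the first NIRt column.
#'
#' @param nirr,nirt [spectral_dataset()]s with identical sample ids and
#'   labels in identical order.
#' @return A fused `spectral_dataset`.
#' @export
fuse <- function(nirr, nirt) {
  if (!identical(nirr$sample_ids, nirt$sample_ids))
    stop("sample ids differ between modalities")
  if (!identical(nirr$y, nirt$y))
    stop("labels differ between modalities")
  if (ncol(nirt$X) == 0) {
    out <- nirr
    out$modality <- "fused"
    out$splice <- NA_integer_
    return(out)
  }
  spectral_dataset(cbind(nirr$X, nirt$X),
                   c(nirr$wavenumbers, nirt$wavenumbers),
                   nirr$y, nirr$sample_ids,
                   modality = "fused",
                   splice = ncol(nirr$X) + 1L)
}

#' Kennard-Stone sample selection
#'
#' Classic deterministic max-min selection: start from the two points at
#' maximal Euclidean distance, then repeatedly add the point whose minimal
#' distance to the already-selected set is largest. Ties are broken by the
#' lowest row index (for the starting pair: lexicographically smallest
#' index pair). The selection order is invariant to row permutation (up to
#' ties) and to adding a constant to all rows.
#'
#' @param X numeric matrix (samples x variables).
#' @param n_select number of samples to select, `2 <= n_select <= nrow(X)`.
#' @return Integer vector of row indices in selection order.
#' @export
kennard_stone <- function(X, n_select) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n_select < 2) stop("n_select must be >= 2")
  if (n_select > n) stop("n_select exceeds the number of samples")
  D <- as.matrix(stats::dist(X))
  # starting pair: max distance, ties -> smallest (i, j) lexicographically
  best <- -Inf; pair <- c(1L, 2L)
  for (i in seq_len(n - 1L)) {
    j <- (i + 1L):n
    m <- max(D[i, j])
    if (m > best) {
      best <- m
      pair <- c(i, i + which(D[i, j] == m)[1])
    }
  }
  sel <- pair
  if (n_select > 2) {
    mind <- pmin(D[, pair[1]], D[, pair[2]])
    mind[sel] <- -Inf
    for (step in 3:n_select) {
      nxt <- which.max(mind)          # ties -> lowest index
      sel <- c(sel, nxt)
      mind <- pmin(mind, D[, nxt])
      mind[nxt] <- -Inf
    }
  }
  as.integer(sel)
}

#' Per-class Kennard-Stone 2:1 train/test split
#'
#' Runs Kennard-Stone independently within each mildew grade on that
#' grade's spectra; the first `round(n_class * train_fraction)` selected
#' samples (round half up, stated explicitly because 154 * 2/3 is
#' non-integral) form the training set, the remainder the test set. With
#' the default 2:1 ratio and class sizes 252/154/254 this gives
#' 168/103/169 training samples. Deterministic.
#'
#' @param ds a [spectral_dataset()]; every class must have >= 3 samples.
#' @param train_fraction training fraction (default 2/3, i.e. a 2:1 split).
#' @return A `split_result` list: `train_indices`, `test_indices` (row
#'   indices into `ds`), and `ratio`.
#' @export
ks_split <- function(ds, train_fraction = 2 / 3) {
  train <- integer(0)
  for (g in GRADE_CODES) {
    idx <- which(ds$y == g)
    if (length(idx) < 3)
      stop("grade ", g, " has ", length(idx), " samples; need >= 3")
    n_tr <- floor(length(idx) * train_fraction + 0.5)  # round half up
    sel <- kennard_stone(ds$X[idx, , drop = FALSE], n_tr)
    train <- c(train, idx[sel])
  }
  train <- sort(train)
  structure(list(train_indices = train,
                 test_indices = setdiff(seq_len(nrow(ds$X)), train),
                 ratio = train_fraction / (1 - train_fraction)),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("<split_result> ", length(x$train_indices), " train / ",
      length(x$test_indices), " test (ratio ",
      format(x$ratio, digits = 3), ":1)\n", sep = "")
  invisible(x)
}
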