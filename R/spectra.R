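#' Spectral dataset container
#'
#' A `spectral_dataset` bundles an absorbance matrix (samples x wavenumber
#' variables), its wavenumber grid in cm^-1, three-level mildew-grade labels
#' and sample identifiers, for one acquisition modality (`"nirr"` diffuse
#' reflectance, `"nirt"` diffuse transmittance) or for the fused
#' representation (`"fused"`, a column-wise concatenation of the two blocks).
#'
#' Grade codes are integers: 0 = normal, 1 = slightly moldy,
#' 2 = seriously moldy.
#'
#' @param X numeric matrix, `n_samples x n_variables`, absorbance
#'   (A = log 1/R convention; unitless).
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   monotone, one per column of `X`. Non-fused grids must be evenly spaced.
#' @param y integer vector of grade codes in `{0, 1, 2}`, one per row of `X`.
#' @param sample_ids character vector of unique sample identifiers; defaults
#'   to `"s1"`, `"s2"`, ...
#' @param modality one of `"nirr"`, `"nirt"`, `"fused"`.
#' @param splice for fused datasets, the 1-based column index where the NIRt
#'   block starts (`NA` otherwise).
#'
#' @return An object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(X, wavenumbers, y,
                             sample_ids = NULL,
                             modality = c("nirr", "nirt", "fused"),
                             splice = NA_integer_) {
  modality <- match.arg(modality)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- if (nrow(X) > 0) paste0("s", seq_len(nrow(X))) else character(0)
  }
  ds <- structure(
    list(X = X, wavenumbers = as.numeric(wavenumbers),
         y = as.integer(y), sample_ids = as.character(sample_ids),
         modality = modality, splice = as.integer(splice)),
    class = "spectral_dataset")
  validate_dataset(ds)
  ds
}

GRADE_CODES <- 0:2
GRADE_NAMES <- c("normal", "slightly moldy", "seriously moldy")

#' Validate a spectral dataset
#'
#' Checks the container invariants: matching dimensions, finite absorbance,
#' admissible grade codes, strictly monotone grid and (for single-modality
#' grids) constant spacing within a relative tolerance of 1e-6, and the
#' printed acquisition ranges (NIRr within 3996--10000 cm^-1, NIRt within
#' 5793--10000 cm^-1).
#'
#' @param ds a [spectral_dataset()].
#' @return `ds`, invisibly; errors describe the violated invariant.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "spectral_dataset"))
  n <- nrow(ds$X); p <- ncol(ds$X)
  if (length(ds$y) != n)
    stop("label count (", length(ds$y), ") != sample count (", n, ")")
  if (length(ds$sample_ids) != n)
    stop("sample_id count (", length(ds$sample_ids), ") != sample count (", n, ")")
  if (length(ds$wavenumbers) != p)
    stop("grid length (", length(ds$wavenumbers), ") != variable count (", p, ")")
  if (anyDuplicated(ds$sample_ids))
    stop("sample_ids are not unique")
  bad <- which(!(ds$y %in% GRADE_CODES))
  if (length(bad))
    stop("invalid grade code ", ds$y[bad[1]], " at row ", bad[1],
         " (admissible codes: 0, 1, 2)")
  if (n > 0 && p > 0 && !all(is.finite(ds$X)))
    stop("non-finite absorbance values present")
  if (p > 1 && ds$modality != "fused") {
    d <- diff(ds$wavenumbers)
    if (!(all(d > 0) || all(d < 0)))
      stop("wavenumber grid is not strictly monotone")
    rel <- abs(d - d[1]) / abs(d[1])
    if (any(rel > 1e-6))
      stop("wavenumber spacing not constant (modality ", ds$modality, ")")
  }
  rng <- switch(ds$modality,
                nirr = c(3996, 10000), nirt = c(5793, 10000), NULL)
  if (!is.null(rng) && p > 0) {
    if (min(ds$wavenumbers) < rng[1] || max(ds$wavenumbers) > rng[2])
      stop(ds$modality, " grid outside [", rng[1], ", ", rng[2], "] cm^-1")
  }
  invisible(ds)
}

#' @export
print.spectral_dataset <- function(x, ...) {
  cat("<spectral_dataset> modality:", x$modality, "\n")
  cat("  ", nrow(x$X), " samples x ", ncol(x$X), " variables\n", sep = "")
  if (ncol(x$X) > 0)
    cat("  wavenumbers: ", min(x$wavenumbers), "-", max(x$wavenumbers),
        " cm^-1\n", sep = "")
  if (!is.na(x$splice)) cat("  splice index (NIRt block start):", x$splice, "\n")
  if (nrow(x$X) > 0) {
    tab <- table(factor(x$y, levels = GRADE_CODES, labels = GRADE_NAMES))
    cat("  grades:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.spectral_dataset <- function(x) dim(x$X)

#' Subset the samples of a dataset
#'
#' @param ds a [spectral_dataset()].
#' @param i row (sample) index vector.
#' @return A `spectral_dataset` with the selected samples.
#' @export
subset_samples <- function(ds, i) {
  out <- ds
  out$X <- ds$X[i, , drop = FALSE]
  out$y <- ds$y[i]
  out$sample_ids <- ds$sample_ids[i]
  out
}

#' Read a spectral dataset from CSV
#'
#' The package's CSV dialect: UTF-8, comma-separated; first two columns are
#' `sample_id` and `grade`, the remaining column headers are the wavenumbers
#' in grid order; one sample per row.
#'
#' @param path file path.
#' @param modality modality tag recorded on the result.
#' @return A [spectral_dataset()].
#' @export
read_dataset <- function(path, modality = c("nirr", "nirt", "fused")) {
  modality <- match.arg(modality)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: ", path)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (length(header) < 2 || header[1] != "sample_id" || header[2] != "grade")
    stop("malformed header: expected 'sample_id,grade,<wavenumbers...>'")
  wn <- suppressWarnings(as.numeric(header[-(1:2)]))
  if (anyNA(wn))
    stop("non-numeric wavenumber in header column ",
         which(is.na(wn))[1] + 2L)
  body <- lines[-1]
  body <- body[nzchar(body)]
  n <- length(body)
  p <- length(wn)
  X <- matrix(NA_real_, n, p)
  y <- integer(n)
  ids <- character(n)
  for (r in seq_len(n)) {
    f <- strsplit(body[[r]], ",", fixed = TRUE)[[1]]
    if (length(f) != p + 2L)
      stop("ragged row ", r, ": ", length(f), " fields, expected ", p + 2L)
    ids[r] <- f[1]
    g <- suppressWarnings(as.integer(f[2]))
    if (is.na(g) || !(g %in% GRADE_CODES))
      stop("unknown grade code '", f[2], "' at row ", r)
    y[r] <- g
    v <- suppressWarnings(as.numeric(f[-(1:2)]))
    if (anyNA(v)) stop("non-numeric absorbance at row ", r,
                       ", column ", which(is.na(v))[1] + 2L)
    X[r, ] <- v
  }
  spectral_dataset(X, wn, y, ids, modality = modality)
}

#' Write a spectral dataset to CSV
#'
#' Inverse of [read_dataset()]: the emitted file re-reads to an equal dataset
#' (absorbance round-trips bit-exactly through a 17-significant-digit
#' decimal representation).
#'
#' @param ds a [spectral_dataset()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  fmt <- function(x) format(x, digits = 17, scientific = FALSE, trim = TRUE)
  header <- paste(c("sample_id", "grade", fmt(ds$wavenumbers)), collapse = ",")
  rows <- character(nrow(ds$X))
  for (r in seq_len(nrow(ds$X))) {
    rows[r] <- paste(c(ds$sample_ids[r], ds$y[r], fmt(ds$X[r, ])),
                     collapse = ",")
  }
  writeLines(c(header, rows), path, useBytes = FALSE)
  invisible(path)
}

#' Drop spectral variables above a wavenumber cut-off
#'
#' Variables above 10,000 cm^-1 are dominated by detector noise in this
#' application and are removed before modelling; column order is preserved
#' and rows are untouched.
#'
#' @param ds a [spectral_dataset()].
#' @param max_wn cut-off in cm^-1 (retain wavenumbers `<= max_wn`).
#' @return The truncated `spectral_dataset`.
#' @export
truncate_above <- function(ds, max_wn = 10000) {
  keep <- which(ds$wavenumbers <= max_wn)
  if (length(keep) == 0)
    stop("truncation at ", max_wn, " cm^-1 removes every variable")
  out <- ds
  out$X <- ds$X[, keep, drop = FALSE]
  out$wavenumbers <- ds$wavenumbers[keep]
  out
}

#' Average front- and back-side replicate spectra
#'
#' Each seed is measured once on its front and once on its back side; the
#' final spectrum is the element-wise mean of the two replicates.
#'
#' @param front,back `spectral_dataset`s with identical grids, sample ids
#'   (in identical order) and labels.
#' @return A `spectral_dataset` with `X = (X_front + X_back) / 2`.
#' @export
average_sides <- function(front, back) {
  if (!identical(front$wavenumbers, back$wavenumbers))
    stop("front/back wavenumber grids differ")
  if (!identical(front$sample_ids, back$sample_ids))
    stop("front/back sample ids differ")
  if (!identical(front$y, back$y))
    stop("front/back labels differ")
  out <- front
  out$X <- (front$X + back$X) / 2
  out
}
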