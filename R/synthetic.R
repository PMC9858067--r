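#' Absorption band specification
#'
#' A Gaussian absorption band in wavenumber space. Its amplitude for a
#' sample of grade g is `base_amplitude + class_deltas[g + 1]` on the
#' modalities listed in `deltas_on`, and `base_amplitude` on any other
#' modality carrying the band. This lets a band be physically present on
#' both grids while its mildew-related intensity change is visible in only
#' one geometry — the complementarity the fused representation exploits.
#'
#' @param center band centre in cm^-1.
#' @param width Gaussian sigma in cm^-1.
#' @param base_amplitude grade-independent amplitude (absorbance units).
#' @param class_deltas numeric length-3 vector of per-grade amplitude
#'   offsets (grades 0, 1, 2).
#' @param modality `"nirr"`, `"nirt"` or `"both"`: which grid(s) carry the
#'   band.
#' @param deltas_on modalities on which `class_deltas` apply (default: all
#'   of `modality`).
#' @return A `band_spec` list.
#' @export
band_spec <- function(center, width, base_amplitude,
                      class_deltas = c(0, 0, 0),
                      modality = c("both", "nirr", "nirt"),
                      deltas_on = NULL) {
  modality <- match.arg(modality)
  if (is.null(deltas_on))
    deltas_on <- if (modality == "both") c("nirr", "nirt") else modality
  stopifnot(width > 0, length(class_deltas) == 3,
            base_amplitude + min(class_deltas) >= 0)
  structure(list(center = center, width = width,
                 base_amplitude = base_amplitude,
                 class_deltas = as.numeric(class_deltas),
                 modality = modality, deltas_on = deltas_on),
            class = "band_spec")
}

#' Per-grade sampling profile
#'
#' Sample count and nuisance scales for one mildew grade. The nuisance
#' terms model exactly what the preprocessing stage is meant to remove:
#' additive linear baseline drift (offset + slope), multiplicative scatter
#' from particle/kernel geometry, white detector noise, and a front/back
#' replicate offset.
#'
#' @param grade grade code (0, 1 or 2).
#' @param n_samples number of seeds of this grade.
#' @param baseline_offset_sd,baseline_slope_sd additive baseline scales
#'   (absorbance units).
#' @param scatter_sd scale of the log-normal multiplicative scatter factor.
#' @param noise_sd additive white-noise sd per variable.
#' @param side_jitter_sd sd of the per-side replicate offset.
#' @return A `class_profile` list.
#' @export
class_profile <- function(grade, n_samples,
                          baseline_offset_sd = 0.08,
                          baseline_slope_sd = 0.03,
                          scatter_sd = 0.12,
                          noise_sd = 0.03,
                          side_jitter_sd = 0.01) {
  stopifnot(grade %in% GRADE_CODES, n_samples >= 0,
            baseline_offset_sd >= 0, baseline_slope_sd >= 0,
            scatter_sd >= 0, noise_sd >= 0, side_jitter_sd >= 0)
  structure(list(grade = as.integer(grade), n_samples = as.integer(n_samples),
                 baseline_offset_sd = baseline_offset_sd,
                 baseline_slope_sd = baseline_slope_sd,
                 scatter_sd = scatter_sd, noise_sd = noise_sd,
                 side_jitter_sd = side_jitter_sd),
            class = "class_profile")
}

#' Synthetic-experiment configuration
#'
#' @param nirr_grid,nirt_grid wavenumber grids (cm^-1), stored high-to-low.
#' @param bands list of [band_spec()] objects.
#' @param profiles list of three [class_profile()]s, one per grade.
#' @param nirt_offset constant absorbance added to all NIRt spectra
#'   (transmittance through the kernel returns less light, so recorded
#'   absorbance is higher than in reflectance); must be positive.
#' @param seed integer seed driving all sampling in [generate_dataset()].
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(nirr_grid, nirt_grid, bands, profiles,
                             nirt_offset = 0.35, seed = 2023L) {
  grades <- vapply(profiles, function(p) p$grade, integer(1))
  if (!identical(sort(grades), GRADE_CODES))
    stop("need exactly one class_profile per grade 0, 1, 2")
  if (nirt_offset <= 0) stop("nirt_offset must be positive")
  structure(list(nirr_grid = as.numeric(nirr_grid),
                 nirt_grid = as.numeric(nirt_grid),
                 bands = bands,
                 profiles = profiles[order(grades)],
                 nirt_offset = nirt_offset,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Default synthetic configuration
#'
#' Emulates the statistical structure of the sunflower-seed application:
#'
#' * grids at 16 cm^-1 spacing covering 3996--9996 cm^-1 (NIRr, 376
#'   variables) and 5793--9985 cm^-1 (NIRt, 263 variables), stored
#'   high-to-low;
#' * class counts 252 / 154 / 254 (normal / slightly / seriously moldy);
#' * an NIRr-exclusive fingerprint region below 5793 cm^-1 with
#'   protein/fat bands whose intensities track the mildew grade: C=O
#'   bending second overtone near 5263 cm^-1 (grows with grade — ketones
#'   and aldehydes from fat breakdown), C-N bending second overtone near
#'   5208 cm^-1 (shrinks with grade — protein degradation), N-H
#'   combination near 4866 cm^-1;
#' * NIRt-informative bands in the short-wavelength region: C-H second
#'   overtones near 8480 and 8250 cm^-1 and an N-H second overtone near
#'   9925 cm^-1, class-dependent only in transmittance (the reflectance
#'   curve stays flat there);
#' * complementary contrasts: the normal-vs-slightly contrast is carried
#'   mainly by the NIRt bands, the slightly-vs-seriously contrast mainly by
#'   the NIRr-exclusive bands, so single-modality models plateau below the
#'   fused model;
#' * a constant positive NIRt absorbance offset, plus baseline drift,
#'   multiplicative scatter, white noise and front/back jitter as nuisance.
#'
#' @param seed seed stored in the config (default 2023).
#' @return A [synthetic_config()].
#' @export
default_config <- function(seed = 2023L) {
  nirr_grid <- rev(3996 + 16 * (0:375))   # 3996..9996, stored descending
  nirt_grid <- rev(5793 + 16 * (0:262))   # 5793..9985, stored descending
  bands <- list(
    # grade-independent matrix background (water, oil, protein bulk)
    band_spec(6900, 300, 0.25, modality = "both"),
    band_spec(8600, 350, 0.15, modality = "both"),
    band_spec(4750, 250, 0.30, modality = "nirr"),
    band_spec(5700, 120, 0.20, modality = "nirr"),
    # NIRr-exclusive mildew markers: strong slightly-vs-seriously contrast
    band_spec(5263, 40, 0.12, c(0,  0.012,  0.060), modality = "nirr"),
    band_spec(5208, 40, 0.15, c(0, -0.010, -0.050), modality = "nirr"),
    band_spec(4866, 40, 0.14, c(0,  0.008,  0.040), modality = "nirr"),
    # NIRt-informative bands: strong normal-vs-slightly contrast; the 8480
    # band exists on both grids but its grade dependence shows only in NIRt
    band_spec(8480, 60, 0.10, c(0, 0.050, 0.060), modality = "both",
              deltas_on = "nirt"),
    band_spec(8250, 40, 0.08, c(0, 0.045, 0.055), modality = "nirt"),
    band_spec(9925, 40, 0.06, c(0, 0.040, 0.048), modality = "nirt"))
  profiles <- list(class_profile(0L, 252L),
                   class_profile(1L, 154L),
                   class_profile(2L, 254L))
  synthetic_config(nirr_grid, nirt_grid, bands, profiles, seed = seed)
}

# Noise-free band sum for one grade on one modality's grid.
band_sum <- function(cfg, grade, modality) {
  grid <- if (modality == "nirr") cfg$nirr_grid else cfg$nirt_grid
  s <- numeric(length(grid))
  for (b in cfg$bands) {
    if (b$modality != "both" && b$modality != modality) next
    amp <- b$base_amplitude +
      if (modality %in% b$deltas_on) b$class_deltas[grade + 1L] else 0
    s <- s + amp * exp(-0.5 * ((grid - b$center) / b$width)^2)
  }
  s
}

#' Noise-free class-mean spectrum
#'
#' The deterministic band sum for one grade on one modality, i.e. the
#' expected spectrum with all nuisance scales at zero (before the NIRt
#' offset is added).
#'
#' @param cfg a [synthetic_config()].
#' @param grade grade code.
#' @param modality `"nirr"` or `"nirt"`.
#' @return Numeric absorbance vector on the modality's grid.
#' @export
class_mean_spectrum <- function(cfg, grade, modality = c("nirr", "nirt")) {
  modality <- match.arg(modality)
  s <- band_sum(cfg, grade, modality)
  if (modality == "nirt") s <- s + cfg$nirt_offset
  s
}

#' Draw one synthetic seed (four spectra)
#'
#' Draws the front and back replicate of both modalities for a single seed
#' of the given grade, consuming the current R random stream. Each
#' replicate is
#' `scatter * band_sum(grade) + baseline + nirt_offset + side_offset + noise`,
#' where `scatter = exp(N(0, scatter_sd))` is shared by the two modalities,
#' the linear baseline (offset + slope over the 0--1 normalised wavenumber)
#' is drawn per modality, the side offset per replicate, and the white
#' noise per replicate and variable. Output is clipped at zero absorbance.
#'
#' @param cfg a [synthetic_config()].
#' @param grade grade code (0, 1, 2).
#' @return A list with numeric vectors `nirr_front`, `nirr_back`,
#'   `nirt_front`, `nirt_back`.
#' @export
generate_sample <- function(cfg, grade) {
  prof <- cfg$profiles[[grade + 1L]]
  scatter <- exp(stats::rnorm(1, 0, prof$scatter_sd))
  one_modality <- function(modality) {
    grid <- if (modality == "nirr") cfg$nirr_grid else cfg$nirt_grid
    u <- (grid - min(grid)) / (max(grid) - min(grid))
    base <- scatter * band_sum(cfg, grade, modality) +
      stats::rnorm(1, 0, prof$baseline_offset_sd) +
      stats::rnorm(1, 0, prof$baseline_slope_sd) * u +
      if (modality == "nirt") cfg$nirt_offset else 0
    side <- function() {
      pmax(0, base + stats::rnorm(1, 0, prof$side_jitter_sd) +
                stats::rnorm(length(grid), 0, prof$noise_sd))
    }
    list(front = side(), back = side())
  }
  r <- one_modality("nirr"); t <- one_modality("nirt")
  list(nirr_front = r$front, nirr_back = r$back,
       nirt_front = t$front, nirt_back = t$back)
}

#' Generate a paired NIRr/NIRt dataset
#'
#' Draws `n_samples` seeds per grade (profile counts), averages the front
#' and back replicates via [average_sides()], and returns the two
#' side-averaged single-modality datasets with aligned sample ids and
#' labels. Fully deterministic given `cfg$seed`.
#'
#' @param cfg a [synthetic_config()]; `cfg$seed` seeds the draw.
#' @return `list(nirr = <spectral_dataset>, nirt = <spectral_dataset>)`.
#' @export
generate_dataset <- function(cfg) {
  set.seed(cfg$seed)
  counts <- vapply(cfg$profiles, function(p) p$n_samples, integer(1))
  n <- sum(counts)
  y <- rep(GRADE_CODES, counts)
  ids <- if (n > 0) sprintf("g%d_%03d", y, unlist(lapply(counts, seq_len_safe)))
         else character(0)
  mk <- function(p) matrix(0, n, p)
  Xrf <- mk(length(cfg$nirr_grid)); Xrb <- Xrf
  Xtf <- mk(length(cfg$nirt_grid)); Xtb <- Xtf
  for (i in seq_len(n)) {
    s <- generate_sample(cfg, y[i])
    Xrf[i, ] <- s$nirr_front; Xrb[i, ] <- s$nirr_back
    Xtf[i, ] <- s$nirt_front; Xtb[i, ] <- s$nirt_back
  }
  nirr <- average_sides(
    spectral_dataset(Xrf, cfg$nirr_grid, y, ids, modality = "nirr"),
    spectral_dataset(Xrb, cfg$nirr_grid, y, ids, modality = "nirr"))
  nirt <- average_sides(
    spectral_dataset(Xtf, cfg$nirt_grid, y, ids, modality = "nirt"),
    spectral_dataset(Xtb, cfg$nirt_grid, y, ids, modality = "nirt"))
  list(nirr = nirr, nirt = nirt)
}

seq_len_safe <- function(n) if (n > 0) seq_len(n) else integer(0)
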