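---
title: "Grading internal seed mildew from fused NIR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading internal seed mildew from fused NIR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Shelled sunflower seeds can mold internally with no external sign; the
affected kernels carry mycotoxin risk but cannot be removed by colour
sorting. Near-infrared spectroscopy sees through the shell: molecular
overtone and combination bands of C–H, N–H and C=O bonds shift in
intensity as mold enzymes break down the kernel's fat and protein. Two
acquisition geometries are available on the same instrument — diffuse
reflectance (NIRr, recorded over 3996–10,000 cm⁻¹), which mostly probes
the kernel near its surface, and diffuse transmittance (NIRt,
5793–10,000 cm⁻¹), which integrates over the optical path through the
kernel. The two geometries carry complementary information, and this
package implements a pipeline that classifies each seed into one of three
ordinal mildew grades (0 = normal, 1 = slightly moldy, 2 = seriously
moldy) from the *fused* spectrum — the column-wise concatenation of the
NIRr and NIRt vectors — with a one-dimensional convolutional network.

The pipeline is: spectra (two sides averaged, variables above
10,000 cm⁻¹ removed) → per-variable Z-score → optional SNV or
Savitzky–Golay first derivative, per modality → fusion → per-class
Kennard–Stone 2:1 train/test split → classifier → repeated-training
evaluation.

## Synthetic data: what the generator emulates

No public spectra exist for this application, so the package ships a
generator (`default_config()`, `generate_dataset()`) that reproduces the
*statistical* structure the pipeline presumes, and every claim the test
suite makes is a claim about data of this structure:

* **Grids and counts.** 16 cm⁻¹ spacing; 376 NIRr variables
  (3996–9996 cm⁻¹) and 263 NIRt variables (5793–9985 cm⁻¹), stored
  high-to-low; class counts 252/154/254 (n = 660).
* **Bands.** Absorption bands are Gaussians in wavenumber (width
  40 cm⁻¹ for the narrow marker bands; the described absorption regions
  are of the order of 100–400 cm⁻¹ wide, so a concrete shape had to be
  chosen). Mildew markers sit where the application's chemistry puts
  them: a C=O bending second overtone near 5263 cm⁻¹ whose amplitude
  *grows* with grade (ketones/aldehydes from fat breakdown), a C–N
  bending second overtone near 5208 cm⁻¹ that *shrinks* with grade
  (protein degradation), and an N–H combination band near 4866 cm⁻¹ —
  all in the NIRr-exclusive fingerprint region below 5793 cm⁻¹ — plus
  C–H second overtones near 8480 and 8250 cm⁻¹ and an N–H second
  overtone near 9925 cm⁻¹ that are grade-dependent only in
  transmittance.
* **Engineered complementarity.** The normal-vs-slightly contrast is
  carried mainly by the NIRt bands, the slightly-vs-seriously contrast
  mainly by the NIRr-exclusive bands. Either single modality therefore
  plateaus on one of the two boundaries and the fused representation
  beats both — the pattern the evaluation reproduces.
* **Nuisance.** Per-sample multiplicative scatter `exp(N(0, 0.12))`,
  additive linear baseline drift (offset sd 0.08, slope sd 0.03
  absorbance units), white detector noise (sd 0.03 per variable), a
  constant +0.35 absorbance offset on NIRt (less transmitted light
  returns to the detector, so recorded absorbance is higher), and a
  small front/back replicate offset (sd 0.01). These are exactly the
  effects SNV (scatter, offsets) and the first derivative (baselines)
  are meant to remove. Absorbance is clipped at zero; a physical sample
  cannot have negative absorbance.

The nuisance scales were fixed once, by calibrating the default
experiment into a realistic accuracy regime — fused-FD in the low-to-mid
90s with the single-modality and untreated arms clearly below — and are
configuration, not constants. What the generator does **not** emulate:
wavelength-correlated (pink) noise, instrument drift between sessions,
water-vapour interference, or any radiative-transfer physics; passing
tests on this generator show the pipeline's statistical machinery works,
not that the accuracy figures transfer to any particular instrument.

## Preprocessing

All three arms standardise each variable first (`zscore_fit()` /
`zscore_apply()`): the Z-score statistics are computed on the **training
rows only** and reused unchanged on the test rows, so no test
information leaks into the standardisation. The per-variable reading of
"zero-mean normalisation" is the standard chemometric one; a
per-spectrum reading exists but then SNV would be redundant.

* **NP** is the Z-score alone.
* **SNV** (`snv()`) centres and scales each spectrum by its own mean and
  sample SD; it removes multiplicative scatter exactly
  (`SNV(a·s + b) = SNV(s)` for `a > 0`) and is idempotent.
* **FD** (`savgol_fd()`) is the Savitzky–Golay first derivative with 17
  smoothing points and polynomial order 2. The kernel comes from the
  least-squares local polynomial fit (and the test suite checks it
  against an explicit per-window least-squares oracle); edges are
  mirror-padded so the output keeps the input length and the two
  modality blocks stay aligned for fusion. The derivative is exact for
  quadratics at interior points.

Preprocessing is applied **per modality, before fusion**: the two
geometries differ in absorbance level and curve morphology, and treating
them separately closes the jump at the splicing site of the fused
vector.

One deliberate default: `sg_scale = FALSE` leaves the derivative per
grid step rather than dividing by the 16 cm⁻¹ spacing. The two differ
only by a constant, but the division shrinks standardised spectra by a
factor ~16, and models with fixed hyperparameters are not
scale-insensitive: the RBF-SVM's default bandwidth (`gamma = 1/p`)
assumes roughly unit-variance features, and the network's initialisation
scale likewise. With per-cm⁻¹ scaling the SVM collapses to
majority-class prediction and the network's logits start an order of
magnitude too small. `sg_scale = TRUE` restores physical units when the
derivative itself is the object of interest.

## The Kennard–Stone split

`ks_split()` runs classic Kennard–Stone — start from the two points at
maximal Euclidean distance, then repeatedly add the point whose minimal
distance to the selected set is largest — independently within each
grade, and takes the first `round(n_class * 2/3)` selections (round half
up; 154·2/3 is non-integral, giving 168/103/169 training seeds) as the
training set. Distances are computed once, on the Z-scored fused
representation, and the same split feeds every arm, so arm comparisons
ride on a common partition. That Z-score is fitted on all samples — it
only shapes the split geometry; the modelling Z-score is refitted on the
training rows. Ties (exactly equal distances) are broken by the lowest
row index, making the split fully deterministic.

## Models

**1D-CNN** (`fit_cnn()`). The stack is
`Conv1D(64 filters, kernel 3, stride 1, ReLU) → MaxPool(3) → Conv1D(64,
3, 1, ReLU) → MaxPool(3) → Flatten → Dense(64, ReLU) → Dropout(0.5) →
Dense(3) → Softmax`; convolutions are valid (no padding) and pooling is
non-overlapping, so lengths evolve as `L → L−2` per convolution and
`L → ⌊L/3⌋` per pool: 639 → 637 → 212 → 210 → 70 → 4480 → 64 → 3 for
the fused input. Training minimises categorical cross-entropy with Adam
(step 10⁻³, batch 32). Weight initialisation, mini-batch order and
dropout masks all derive from one seed, so a fit is exactly reproducible
under single-threaded linear algebra. The forward/backward passes are
implemented in C++ (RcppArmadillo) with the batch kept in a
(sample, position) × filter layout, which turns each convolution into
one matrix product.

Two defaults deserve comment. *Epochs*: 20 — on the synthetic task the
loss plateaus by epoch ~10, and 20 epochs keep the full 8-repeat,
multi-arm protocol within minutes; the epoch count is configuration and
the accuracy/loss history is recorded per epoch. *Output head*: the
architecture as printed places a ReLU on the 3-unit layer ahead of the
softmax. That variant is available (`relu_output = TRUE`) and tested,
but it is not the default, because it admits a catastrophic failure
mode: if all three logits are simultaneously pushed negative — which
dropout noise reliably does on low-contrast inputs — the ReLU gradient
mask zeroes every learning signal and the network is permanently stuck
at majority-class prediction (reproducible across seeds on the NP and
SNV arms). The default head is the standard linear-logit softmax.

**ANN** (`fit_ann()`). The conventional comparator: one hidden layer of
100 sigmoid units regressed on the grade codes 0/1/2 by full-batch
gradient descent with momentum 0.9 and an adaptive learning rate
(initial 0.1, grown 1.05× after an improving step, shrunk 0.7× with the
step rejected when the MSE worsens by more than 4% — the classic
variable-rate scheme of conventional neural-network toolboxes; plain
fixed-rate descent moves this 639-input network almost nowhere within
the iteration budget). At most 1000 iterations, early stop at
MSE ≤ 0.001. The output unit is `2·sigmoid`, spanning the
grade range while keeping every layer sigmoid. Predictions use the
deviation rule (`ann_decide()`): the assigned label is the nearest grade
code, and a prediction counts as correct only when the raw output lies
strictly within 0.5 of the true code.

**SVM** — RBF kernel, penalty C = 0.8, via libsvm (`e1071`), which does
one-vs-one multiclass. The kernel width follows the scale-adaptive
policy `gamma = 1/(p · var(X))`: it reduces to the classic `1/p` on
unit-variance features but stays calibrated when a pretreatment changes
the feature scale (with fixed `1/p` the kernel degenerates on
derivative-scale features and the classifier collapses to the majority
class). **KNN** — Euclidean, k = 3,
with deterministic tie-breaks (majority vote; vote ties resolved by the
nearest neighbour among the tied classes, then the lowest code), so both
comparators are exactly reproducible across refits and are reported
without SD.

## Evaluation protocol

`repeat_protocol()` trains the configured model eight times (seeds
`base_seed … base_seed+7`) on the *fixed* split — the split is
deterministic, so the repeats vary only training randomness — and
reports the mean ± sample SD of prediction accuracy
(`PA = 100·N_correct/N`) and support-weighted F1 on both sets. Confusion
matrices are averaged as counts across repeats and then converted to row
percent (rows = true grade; each row sums to 100), whose diagonal is the
per-grade accuracy. A class never predicted and never recovered
contributes F1 = 0; for a single repeat the SD is reported as 0 and
flagged undefined. For learned-feature inspection, `extract_features()`
returns the 64-unit dense-layer activations and `tsne_map()` embeds them
in 2-D (exact t-SNE with perplexity bisection, default perplexity 30,
seeded; quadratic cost, fine for hundreds of samples).

`run_experiment()` wires the whole grid from one configuration (R object
or YAML; `inst/config/full_grid.yaml` holds the full 3 × 3 grid), shares the
split across arms, records per-arm mean ± SD metrics, and — given an
output directory — writes a summary JSON, mean confusion matrices and
CNN accuracy/loss histories. An arm that errors is recorded as failed and
the grid continues. Rerunning the same configuration reproduces the
summary byte-identically under single-threaded execution.

## Numerical choices and degenerate inputs

* Zero-variance variables (Z-score) and constant spectra (SNV) are
  errors naming the offending variable/sample, not silent NaNs.
* Savitzky–Golay requires a uniform grid and a window no longer than the
  spectrum; the mirror-padding edge policy is declared rather than
  hidden.
* Softmax rows are max-shifted before exponentiation; cross-entropy
  clips probabilities at 10⁻¹².
* Kennard–Stone and KNN tie-breaks are by lowest index / nearest-tied
  class, chosen purely for determinism.
* The 2:1 rounding rule is round-half-up, stated because one class count
  is non-integral under 2/3.

## Problem sizes used by the tests

Unit tests run on a compact generator configuration (40 + 30 variables,
~66 samples) so the whole suite stays fast; the acceptance tests run the
full default conditions — 660 samples, 639 fused variables, four
modality × pretreatment arms, 8 repeats each — once and share the
result across checks. These sizes are the package's own test-design
choice and are configuration, not limits.

## Known limitations

* The generator's band amplitudes and nuisance scales are plausible, not
  fitted to measured spectra; absolute accuracies on real instruments
  will differ.
* The ANN comparator is a first-order method; on ill-conditioned inputs
  it can exhaust its iteration budget well above the MSE target.
* t-SNE is the exact O(n²) algorithm; use a subsample beyond a few
  thousand points.
* Single-threaded BLAS is assumed for bit-level reproducibility of CNN
  fits; multi-threaded BLAS may reorder floating-point sums.
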