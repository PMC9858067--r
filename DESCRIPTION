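Package: mildewfusion
Title: Mildew Grading of Sunflower Seeds from Fused NIR Reflectance and
    Transmittance Spectra with a 1D Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Non-destructive grading of internal mildew in shelled sunflower
    seeds from near-infrared spectra. Implements the full chemometric
    pipeline: paired diffuse-reflectance (NIRr) and diffuse-transmittance
    (NIRt) spectral datasets, Z-score / standard normal variate (SNV) /
    Savitzky-Golay first-derivative preprocessing, block-wise spectral
    fusion, per-class Kennard-Stone 2:1 sample-set partitioning, a
    one-dimensional convolutional neural network classifier with
    conventional comparators (ANN, RBF-SVM, KNN), and a repeated-training
    evaluation protocol (prediction accuracy, weighted F1, mean confusion
    matrices, t-SNE feature maps). Includes a synthetic spectra generator
    emulating the class-dependent absorption-band structure of the
    application so the pipeline is fully testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    e1071,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
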