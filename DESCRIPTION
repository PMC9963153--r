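Package: sersdecoder
Title: Decoding Bacterial-Lysate SERS Spectra for Heavy-Metal Water Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for surface-enhanced Raman scattering (SERS)
    spectra of bacterial lysate used as a whole-cell sensor of heavy-metal
    contamination in water. Provides a synthetic spectrum generator with
    dose-responsive metabolite bands, asymmetric-least-squares baseline
    correction, Savitzky-Golay smoothing and silicon internal-standard
    normalization, PCA feature reduction with leakage-safe SMOTE class
    balancing, support-vector-machine concentration and metal-type
    classification with a classification-based limit of detection, a
    one-dimensional convolutional neural network concentration regressor with
    empirical limit-of-blank/detection/quantification rules, transfer learning
    to new water matrices with frozen convolutional layers, and exact dosimetry
    conversions between salt mass concentration, ion molarity and
    ions-per-bacterium ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
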