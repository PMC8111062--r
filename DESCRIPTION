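Package: spectriage
Title: Simulation and Diagnostic-Accuracy Analysis for Spectroscopic Liquid Biopsies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying consensus-vote diagnostic tests built on serum
    attenuated total reflectance Fourier-transform infrared (ATR-FTIR)
    spectroscopy, as used for brain-tumour triage of symptomatic patients.
    Provides a seeded generator of synthetic spectral cohorts with the
    triplicate-well, triplicate-scan replicate structure (nine spectra per
    patient), a chemometric preprocessing pipeline (region selection, polynomial
    or rubberband baseline correction, Savitzky-Golay smoothing, normalisation),
    patient-grouped cross-validated classifiers, majority-vote aggregation of
    per-spectrum predictions into patient-level diagnoses with ROC threshold
    sweeping, and diagnostic-accuracy reporting: confusion matrices, sensitivity,
    specificity, predictive values and accuracy with binomial confidence
    intervals, precision (confidence-interval half-width) and sample-size
    calculations, and prevalence-transported predictive values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
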