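Package: ringaf
Title: Photoplethysmography-Based Atrial Fibrillation Screening Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting atrial fibrillation from single-channel
    photoplethysmography (PPG) recordings. Provides a synthetic PPG cohort
    generator (sinus rhythm with respiratory modulation and premature beats,
    atrial fibrillation with structureless intervals and pulse-deficit
    amplitude modulation), the preprocessing chain (0.2-18 Hz zero-phase
    bandpass, resampling to 50 Hz, overlapped window segmentation),
    pulse-peak detection and rhythm-variability features (RMSSD, Shannon
    entropy, autocorrelation, coefficient of variation, pulse rate), linear
    support vector machine and one-dimensional convolutional neural network
    classifiers with temperature-scaled diagnostic confidence, and a
    diagnostic-accuracy evaluation protocol: repeated subject-level
    cross-validation, sensitivity/specificity/PPV/NPV/accuracy, ROC AUC with
    bootstrap confidence intervals, sample-length and decile stratification
    studies, confidence-threshold filtering, and external validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
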