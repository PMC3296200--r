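Package: epifd
Title: Seizure Onset Detection from EEG by ICA and Higuchi Fractal Dimension
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for epileptic-seizure onset detection in
    multichannel EEG (and single-channel ECG) recordings. Provides a
    moving-average prefilter, FastICA blind source separation by deflation,
    a Higuchi fractal-dimension estimator with regression standard errors,
    sliding-window fractal-dimension time-courses, selection of the main
    (highest-FD) independent component, and detection of the seizure onset
    as the minimal drop in the fractal dimension. Includes seeded synthetic
    generators (fractional Gaussian noise and Brownian motion, non-Gaussian
    source mixtures, seizure-like recordings with ground truth) for
    calibration and verification, EDF and CSV input/output, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
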