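Package: fSampEn
Title: Fixed Sample Entropy for Respiratory Muscle EMG and MMG Amplitude
    Estimation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fixed sample entropy (fSampEn) computes sample entropy in a
    moving window with a tolerance held fixed across windows and signals, so
    that the resulting time-series tracks the amplitude of complex,
    noise-like muscle activity while remaining comparatively insensitive to
    quasi-deterministic cardiac transients (ECG/MCG). The package provides
    the fSampEn estimator with an Rcpp kernel, the signal-conditioning chain
    for oesophageal/surface electromyograms and accelerometer
    mechanomyograms (resampling, zero-phase Butterworth band-pass, power-line
    notching comb, auxiliary notches, accelerometer vector norm), breath
    segmentation from mouth pressure by zero-crossing detection,
    individual/global tolerance calibration from inspiratory-segment standard
    deviations, evaluation of (window length, r, SD) parameter grids by
    maximum normalized cross-covariance against respiratory pressures, a
    seeded synthetic respiratory-subject simulator for end-to-end testing,
    and delimited-text/EDF multichannel IO with a thin command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3),
    methods
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
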