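Package: nirsbci
Title: Simulation and Single-Trial Classification of fNIRS Workload Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying single-trial mental-workload detection with
    functional near-infrared spectroscopy (fNIRS). Provides a seeded simulator
    of block-design prefrontal recordings (hemodynamic response, physiological
    noise, common-mode motion artifacts, forward optics), conversion of
    two-wavelength optical-density changes to hemoglobin concentration changes
    via the modified Beer-Lambert law, the standard preprocessing chain
    (Savitzky-Golay low-pass detrending and smoothing, correlation-based
    motion-artifact correction), three workload classifiers (reference-channel
    thresholding, per-timepoint support vector machine, full-timecourse
    support vector machine) under a uniform fit/predict contract, and an
    evaluation protocol with per-participant cross-validation, onset-latency
    statistics, and group tests against chance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
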