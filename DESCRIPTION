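Package: sleepmotion
Title: Multi-Scale Sleep Quality Evaluation from Bed-Sensor Motion Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for unobtrusive sleep-quality assessment from multichannel
    pressure bed sensor recordings. Conditions raw channel matrices into a
    normalized motion envelope (sliding raised-cosine standard deviation or
    PCA), classifies every second of the night into absence, quiet sleep,
    disrupted sleep or displacement via two power thresholds and a minimum
    quiet-sleep duration, summarizes fragmentation through the cumulative
    histogram of quiet-sleep periods and detrended fluctuation analysis
    (Hurst exponent), and evaluates the derived indexes against clinical
    metrics (sleep efficiency, apnea-hypopnea index) with Pearson
    correlation, leave-one-out cross-validation, Bland-Altman agreement and
    Mann-Whitney tests. A synthetic recording generator with second-level
    ground truth supports end-to-end validation, including grid-search
    recovery of the segmentation parameters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
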