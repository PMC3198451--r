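Package: erpmon
Title: Simulation and Analysis of Performance-Monitoring ERPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates an adaptive tactile time-estimation task with
    interspersed stop-signal trials, generates synthetic event-locked
    multichannel EEG epochs containing feedback-related negativity (FRN),
    stop-signal N2 and error-related negativity (ERN) components, and
    provides the analysis chain for quantifying them: common-average
    referencing, baseline correction, condition averaging and difference
    waves, peak and trough-to-peak component measurement, global map
    dissimilarity (GMD) permutation tests on scalp topographies, split-half
    reliability with Spearman-Brown correction, and standardized bivariate
    regressions between component amplitudes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
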