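Package: dictime
Title: Dictation-Time Analysis from Radiology Information System Timestamps
Version: 0.1.0
Authors@R: person("dictime", "maintainers", email = "dictime@example.org", role = c("aut", "cre"))
Description: Computes radiological dictation times from Radiology Information
    System (RIS) timestamp exports, removes contextual outliers (interrupted
    or paused-and-resumed reports) by fitting a contaminated-normal mixture
    with either a reference expectation-maximization algorithm or an
    iterative stochastic parameter-vector search, and reports per-region
    descriptive statistics, normality diagnostics, two-group comparisons and
    a confidence-interval-width sample-size calculator. Includes a synthetic
    dictation-time generator with known ground truth and a command-line
    pipeline producing summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
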