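Package: wktap
Title: Wing-Kristofferson Analysis of Synchronization-Continuation Tapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for paced and self-paced finger-tapping experiments analysed
    under the Wing-Kristofferson two-process timing model extended with
    polynomial drift. Reads and writes flat tap-log and cohort tables,
    simulates synchronization-continuation sessions (independent clock
    intervals and motor delays, drift in the mean interval, missed and double
    taps), estimates per-participant timing metrics (clock, motor and total
    variance, modelled mean inter-response interval, drift and absolute drift)
    from a drift-detrended lag-1 autocovariance fit with residual-based tap
    exclusion, and compares groups with covariate-adjusted regressions and
    bias-corrected and accelerated (BCa) bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tibble,
    sandwich,
    lmtest,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
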