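Package: cptboot
Title: Two-Stage Multiple Change-Point Detection with Bootstrap
    Confidence Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detection of multiple change points in the coefficients of a
    linear regression model by a two-stage procedure: the series is cut
    into blocks and change-bearing blocks are found by variable selection
    on a cumulative block design (orthogonal greedy algorithm with a
    high-dimensional information criterion stopping rule and a trimming
    step), then each selected two-block window is refined by the argmax of
    a sup-Wald scan.  Segment-wise centered residual bootstrap yields
    pointwise and Bonferroni-joint confidence intervals for the
    change-point locations.  Includes synthetic-data generators for
    piecewise linear regression (optionally with lagged-response
    regressors), Monte-Carlo drivers for detection-accuracy and
    bootstrap-coverage studies, and CSV/JSON input and output helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
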