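Package: risize
Title: Bootstrap Estimation of the Minimum Sample Size for Clinical
    Reference Intervals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the minimum number of reference subjects needed to
    establish a stable clinical reference interval (RI) for a laboratory
    analyte, for both the Box-Cox transformed parametric and the
    non-parametric RI estimators. A two-layer nested loop sweeps candidate
    sample sizes, bootstraps the 90% confidence intervals of both reference
    limits at each size, and declares convergence when the confidence
    interval widths are stably below 0.2 times the RI width (moving-sum and
    moving-median stabilization over a window of 10). Includes Tukey outlier
    filtering, Lilliefors normality assessment, Box-Cox machinery, a
    synthetic reference-population generator with analytically known true
    intervals, and readers for delimited analyte tables and GCT expression
    matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    nortest,
    stats,
    utils
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
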