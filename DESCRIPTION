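Package: shiftdetector
Title: Break-Point Detection for Density-Dependent Population Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects abrupt shifts in the parameters governing
    density-dependent population dynamics from annual abundance time
    series. Fits a Ricker model independently to every admissible
    segmentation of the series by exhaustive enumeration, ranks
    break-point combinations by summed small-sample-corrected Akaike
    information (AICc), and summarises the evidence for each candidate
    break with Akaike weights and per-break weights. Includes a
    stochastic Ricker simulator with step changes in growth rate and
    carrying capacity, and a benchmarking harness measuring detection
    accuracy and break-weight separation across simulation scenario
    grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
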