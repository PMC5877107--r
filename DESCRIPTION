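Package: qcseg
Title: Change-Point Detection for Quality-Control Time Series by Optimal
    Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects abrupt mean shifts (change points) in one-dimensional
    quality-control time series, such as longitudinal phantom metabolite
    levels from magnetic resonance spectroscopy scanners. Segmentation is
    exact, by dynamic programming over seven alternative block-scoring
    functions; the number of change points is chosen by the Bayesian
    Information Criterion; change-point locations carry residual-bootstrap
    confidence intervals; reports include per-interval statistics and
    correction percentages. Also provides the transmitter/receiver gain
    correction for raw metabolite levels, a heteroscedastic piecewise-constant
    simulator, a greedy binary-segmentation baseline, and an error-versus-K
    benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
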