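Package: hurstlab
Title: Hurst Exponent Estimation, Reliability, and Power Analysis for Short Gait Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the Hurst exponent of short stationary time series,
    such as stride-interval and joint range-of-motion series from walking
    trials, by two methods: Detrended Fluctuation Analysis (DFA) and a
    Bayesian Hurst-Kolmogorov process estimator (HKp) that samples the
    marginal posterior of H by accept-reject and reports the median of 50
    draws. Includes an exact fractional Gaussian noise simulator
    (Davies-Harte circulant embedding), a synthetic multi-day gait cohort
    generator with controllable variance components, between-day ICC(3,k)
    reliability grids over stride counts and trials averaged, and a
    Monte-Carlo engine for statistical power and minimum-sample-size
    estimation in two-group designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
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
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
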