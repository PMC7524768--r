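Package: hybridcast
Title: Quantifying Machine Influence on Human Forecasters in Hybrid
    Forecasting Tournaments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing hybrid human-machine forecasting
    tournaments in which a treatment group of forecasters sees a
    time-series model's probabilistic forecast and a control group does
    not.  Implements DeGroot-style belief combination, maximum-likelihood
    estimation of the weight forecasters place on their prior beliefs
    versus the machine advice, ordinal and density Brier scoring,
    cognitive covariates (uncertainty, difficulty, confirmation,
    helpfulness, lifetime, distance, machine reputation), cell-means
    regressions of the influence weight on standardized covariates, and a
    counterfactual coefficient-sweep framework measuring the accuracy
    impact of each cognitive factor.  Includes a synthetic tournament
    generator with planted influence weights so the whole pipeline is
    testable end to end.
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
    yaml
Suggests:
    sandwich,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
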