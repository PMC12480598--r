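Package: deltadisp
Title: Mean-Independent Dispersion for Bounded Continuous Variables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring statistical dispersion of bounded continuous
    variables independently of the mean. Implements the dispersion measure
    delta (variance normalised by the mean's distance to the variable's
    bounds), closed-form heterogeneity measures (standard deviation, variance,
    coefficient of variation, Gini coefficient, differential entropy, 0.95
    quantile range) for beta- and gamma-distributed variables with arbitrary
    bounds, finite-sample estimators of all measures, mean-balanced sampling
    and bias-model comparison with equivalence testing of mean-independence,
    and a simulation suite demonstrating how mean-biased heterogeneity
    measures generate spurious heterogeneity-diversity relationships in
    ecological regressions.
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
    utils
Suggests:
    broom,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
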