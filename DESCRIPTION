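Package: maxtcomp
Title: Max-t Simultaneous Inference for Group Means under Heteroscedasticity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simultaneous inference for multiple comparisons of group means
    in unbalanced one-way layouts with unequal variances. Fits the cell-means
    linear model by ordinary least squares, estimates the coefficient
    covariance with heteroscedasticity-consistent sandwich estimators
    (HC0-HC3), and refers the maximum absolute standardized contrast
    statistic to its joint multivariate normal or t reference distribution,
    computed by randomized quasi-Monte Carlo integration. Provides
    single-step adjusted p-values and simultaneous confidence intervals for
    Tukey all-pairwise, Dunnett many-to-one and user-specified contrasts,
    a Tukey-Kramer implementation for comparison, and a simulation engine
    estimating familywise error rate and power under configurable
    heteroscedastic scenarios.
License: MIT
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
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    multcomp,
    mvtnorm,
    optparse,
    pracma,
    sandwich,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
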