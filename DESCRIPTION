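Package: timeprior
Title: Bayesian Central-Tendency Analysis of Time-Interval Reproduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying central tendency (regression to the mean) in
    time-interval reproduction through the lens of a Bayesian ideal observer.
    Provides the closed-form Gaussian observer algebra (posterior mean and
    width, predicted reproduction slope, prior-width inversion from a
    regression index and a Weber fraction), a seeded trial-level simulator of
    the ready-set-go reproduction paradigm with motor noise, generators for
    synthetic observer cohorts and two-alternative forced-choice time
    discrimination data, estimators for every derived measure (regression
    index, BIAS/CV error partition, Weber fraction from a cumulative-Gaussian
    psychometric fit, context dependency, split-half regression build-up,
    Cohen's d), and Monte-Carlo machinery for model-prediction grids, the
    relative-error landscape over Weber fraction and prior width, and
    optimal-prior search. Results are tibbles designed for piped workflows,
    with broom-style tidy() and glance() methods and ggplot2 autoplot()
    figures.
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
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
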