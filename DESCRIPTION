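Package: zoipanc
Title: Zero-and-One-Inflated Poisson Modelling of Skilled Antenatal Care Visit Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing counts of skilled antenatal care (SANC) visits
    from pooled household-survey data. Implements the zero-and-one-inflated
    Poisson (ZOIP) distribution and its log-linear regression via maximum
    likelihood, a partial score test for simultaneous inflation at zero and
    one, nonparametric bivariate screening (Kruskal-Wallis with pairwise
    Mann-Whitney follow-up), delta-method confidence intervals for
    residence-by-survey-year interaction contrasts, and a synthetic survey
    generator with known ground truth for end-to-end validation.
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
    numDeriv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
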