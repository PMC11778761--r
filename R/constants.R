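# Canonical covariate levels, survey-year coding and published-report defaults.
# Reference level first in every vector; design-matrix column order is fixed
# so coefficient vectors are comparable across runs.

#' Canonical covariate levels
#'
#' Named list of the categorical covariates used throughout the package, each
#' a character vector of levels with the regression reference level first.
#' The outcome column `sanc_visits` and the `survey_year` label are handled
#' separately.
#'
#' @return Named list of character vectors.
#' @export
#' @examples
#' sanc_levels()$wealth
sanc_levels <- function() {
  list(
    residence            = c("urban", "rural"),
    maternal_age         = c("<20", "20-34", ">34"),
    maternal_edu         = c("none", "primary", "secondary", "higher"),
    paternal_edu         = c("none", "primary", "secondary", "higher"),
    wealth               = c("poor", "middle", "rich"),
    birth_order          = c("first", "second_third", "above_third"),
    working              = c("non_working", "working"),
    media                = c("non_exposed", "exposed"),
    decision             = c("no", "yes"),
    violence_opinion     = c("non_justified", "justified"),
    wanted_pregnancy     = c("no", "yes"),
    terminated_pregnancy = c("no", "yes")
  )
}

# Survey-year labels and their quantitative coding (1-4).
.sanc_years <- c("2011" = 1, "2014" = 2, "2017-18" = 3, "2022" = 4)

#' Survey-year labels and numeric coding
#'
#' The four pooled survey waves and the quantitative code used for the
#' trend term in the regression: 1 for 2011, 2 for 2014, 3 for 2017-18
#' and 4 for 2022.
#'
#' @return Named numeric vector; names are the year labels.
#' @export
sanc_year_codes <- function() .sanc_years

# Normalize year labels: accept en-dash variant "2017–18".
normalize_year <- function(x) {
  x <- as.character(x)
  x[x == "2017–18"] <- "2017-18"
  x
}

# Fixed design-matrix column order (22 columns): intercept, 19 dummies,
# year code, rural-by-year interaction.
.design_columns <- c(
  "(Intercept)",
  "residence_rural",
  "age_20_34", "age_over34",
  "medu_primary", "medu_secondary", "medu_higher",
  "pedu_primary", "pedu_secondary", "pedu_higher",
  "wealth_middle", "wealth_rich",
  "birth_second_third", "birth_above_third",
  "working_working",
  "media_exposed",
  "decision_yes",
  "violence_justified",
  "wanted_yes",
  "terminated_yes",
  "year_code",
  "rural_x_year"
)

# Published pooled-analysis regression coefficients (log-mean scale), used
# as the synthetic generator's default truth.
.report_beta <- c(
  "(Intercept)"        = 0.103,
  residence_rural      = -0.523,
  age_20_34            = 0.032,
  age_over34           = 0.148,
  medu_primary         = 0.326,
  medu_secondary       = 0.490,
  medu_higher          = 0.618,
  pedu_primary         = 0.079,
  pedu_secondary       = 0.201,
  pedu_higher          = 0.316,
  wealth_middle        = 0.125,
  wealth_rich          = 0.211,
  birth_second_third   = -0.032,
  birth_above_third    = -0.222,
  working_working      = 0.077,
  media_exposed        = 0.243,
  decision_yes         = 0.087,
  violence_justified   = -0.061,
  wanted_yes           = 0.140,
  terminated_yes       = 0.104,
  year_code            = 0.034,
  rural_x_year         = 0.114
)

.report_phi0 <- 0.172
.report_phi1 <- 0.011

.report_n_per_year <- c("2011" = 6956, "2014" = 4304, "2017-18" = 4819, "2022" = 4712)

# Per-year covariate marginals (column percentages) from the pooled BDHS
# descriptive table; order of probabilities follows sanc_levels() with the
# reference level first. The 2022 terminated-pregnancy column prints
# 18.1/89.9 in the source table (sums past 100); marginals are renormalized
# at use, so the vector is stored as printed.
.report_marginals <- list(
  residence = list(
    "2011" = c(urban = 31.6, rural = 68.4),
    "2014" = c(urban = 32.2, rural = 67.8),
    "2017-18" = c(urban = 34.4, rural = 65.6),
    "2022" = c(urban = 32.9, rural = 67.1)
  ),
  maternal_age = list(
    "2011" = c("<20" = 25.8, "20-34" = 68.5, ">34" = 5.7),
    "2014" = c("<20" = 28.0, "20-34" = 67.4, ">34" = 4.6),
    "2017-18" = c("<20" = 24.2, "20-34" = 71.2, ">34" = 4.6),
    "2022" = c("<20" = 19.1, "20-34" = 74.7, ">34" = 6.2)
  ),
  maternal_edu = list(
    "2011" = c(none = 17.8, primary = 29.7, secondary = 43.7, higher = 8.8),
    "2014" = c(none = 13.1, primary = 27.1, secondary = 48.0, higher = 11.8),
    "2017-18" = c(none = 6.1, primary = 27.5, secondary = 47.9, higher = 18.4),
    "2022" = c(none = 5.2, primary = 22.8, secondary = 52.6, higher = 19.4)
  ),
  paternal_edu = list(
    "2011" = c(none = 26.5, primary = 28.9, secondary = 30.2, higher = 14.4),
    "2014" = c(none = 22.4, primary = 30.0, secondary = 31.9, higher = 15.7),
    "2017-18" = c(none = 13.7, primary = 33.5, secondary = 33.1, higher = 19.8),
    "2022" = c(none = 14.5, primary = 29.6, secondary = 34.7, higher = 21.2)
  ),
  wealth = list(
    "2011" = c(poor = 39.8, middle = 19.2, rich = 41.0),
    "2014" = c(poor = 39.5, middle = 19.2, rich = 41.3),
    "2017-18" = c(poor = 41.6, middle = 18.0, rich = 40.4),
    "2022" = c(poor = 40.5, middle = 19.8, rich = 39.7)
  ),
  birth_order = list(
    "2011" = c(first = 33.9, second_third = 47.6, above_third = 18.6),
    "2014" = c(first = 40.7, second_third = 45.5, above_third = 13.8),
    "2017-18" = c(first = 38.0, second_third = 50.0, above_third = 12.0),
    "2022" = c(first = 37.1, second_third = 53.3, above_third = 9.6)
  ),
  working = list(
    "2011" = c(non_working = 90.2, working = 9.8),
    "2014" = c(non_working = 78.6, working = 21.4),
    "2017-18" = c(non_working = 62.7, working = 37.3),
    "2022" = c(non_working = 74.8, working = 25.2)
  ),
  media = list(
    "2011" = c(non_exposed = 34.3, exposed = 65.7),
    "2014" = c(non_exposed = 37.4, exposed = 62.6),
    "2017-18" = c(non_exposed = 35.8, exposed = 64.2),
    "2022" = c(non_exposed = 40.4, exposed = 59.6)
  ),
  decision = list(
    "2011" = c(no = 24.9, yes = 75.1),
    "2014" = c(no = 27.3, yes = 72.7),
    "2017-18" = c(no = 15.0, yes = 85.0),
    "2022" = c(no = 18.4, yes = 81.6)
  ),
  violence_opinion = list(
    "2011" = c(non_justified = 67.3, justified = 32.7),
    "2014" = c(non_justified = 71.8, justified = 28.2),
    "2017-18" = c(non_justified = 82.0, justified = 18.0),
    "2022" = c(non_justified = 88.2, justified = 11.8)
  ),
  wanted_pregnancy = list(
    "2011" = c(no = 13.4, yes = 86.6),
    "2014" = c(no = 10.1, yes = 89.9),
    "2017-18" = c(no = 8.2, yes = 91.8),
    "2022" = c(no = 7.4, yes = 92.6)
  ),
  terminated_pregnancy = list(
    "2011" = c(no = 81.9, yes = 18.1),
    "2014" = c(no = 85.2, yes = 14.8),
    "2017-18" = c(no = 83.0, yes = 17.0),
    "2022" = c(no = 89.9, yes = 18.1)
  )
)

#' Published regression coefficients used as generator defaults
#'
#' The pooled-analysis ZOIP regression estimates (log-mean scale) in the
#' package's fixed design-matrix column order, together with the inflation
#' masses. These are the default ground truth of [zoip_synth_config()].
#'
#' @return List with elements `beta` (named numeric, length 22), `phi0`,
#'   `phi1`.
#' @export
#' @examples
#' report_coefficients()$phi0
report_coefficients <- function() {
  list(beta = .report_beta, phi0 = .report_phi0, phi1 = .report_phi1)
}
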