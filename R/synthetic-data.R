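# Synthetic pooled-survey generator with known ground truth.
#
# Emulates the pooled four-wave survey: per-year covariate marginals from
# the published percent-distribution table (covariates drawn independently
# within year — only marginals are published, so independence is a stated
# simplification), outcomes from the ZOIP mixture with a log-linear
# Poisson mean driven by the published regression coefficients, and
# optional missingness injected completely at random. One master seed;
# per-stage child seeds are derived deterministically so each stage is
# reproducible on its own.

derive_seed <- function(seed, stage) {
  (abs(seed) %% 100000L) * 10007L + stage * 97L + 13L
}

#' Configuration for the synthetic pooled-survey generator
#'
#' Defaults reproduce the published study conditions: per-year sample
#' sizes 6956/4304/4819/4712 (pooled n = 20791), per-year covariate
#' marginals from the percent-distribution table, regression coefficients
#' from the pooled ZOIP fit, and inflation masses phi0 = 0.172,
#' phi1 = 0.011. Marginal vectors are renormalized to sum to 1 (one
#' published 2022 column sums past 100; the generator flags it).
#'
#' @param n_per_year Named or positional counts for the four survey waves.
#' @param marginals Per-covariate, per-year category probability vectors;
#'   defaults to the published marginals.
#' @param beta Named coefficient vector in design-matrix column order.
#' @param phi0,phi1 Inflation masses.
#' @param seed Master integer seed.
#' @param missing_rate Per-field probability of injected missingness:
#'   a scalar applied to every covariate field, or a named vector for
#'   specific fields. Default 0.
#' @return Object of class `zoip_synth_config`.
#' @export
zoip_synth_config <- function(n_per_year = NULL, marginals = NULL,
                              beta = NULL, phi0 = NULL, phi1 = NULL,
                              seed = 1L, missing_rate = 0) {
  n_per_year <- if (is.null(n_per_year)) .report_n_per_year else {
    if (length(n_per_year) != 4) stop("n_per_year must have 4 entries", call. = FALSE)
    stats::setNames(as.integer(n_per_year), names(.sanc_years))
  }
  marginals <- marginals %||% .report_marginals
  beta <- beta %||% .report_beta
  if (length(beta) != length(.design_columns)) {
    stop("beta must have one entry per design column (",
         length(.design_columns), ")", call. = FALSE)
  }
  names(beta) <- .design_columns
  phi0 <- phi0 %||% .report_phi0
  phi1 <- phi1 %||% .report_phi1
  check_masses(phi0, phi1, allow_boundary = TRUE)

  lev <- sanc_levels()
  for (v in names(lev)) {
    for (yr in names(.sanc_years)) {
      m <- marginals[[v]][[yr]]
      if (length(m) != length(lev[[v]])) {
        stop(sprintf("marginal for %s in %s has wrong length", v, yr),
             call. = FALSE)
      }
      if (abs(sum(m) - 100) > 0.5 && abs(sum(m) - 1) > 0.005) {
        rlang::inform(sprintf(
          "marginal for %s in %s sums to %.1f; renormalizing", v, yr, sum(m)))
      }
      marginals[[v]][[yr]] <- m / sum(m)
    }
  }
  if (is.null(names(missing_rate)) && length(missing_rate) != 1) {
    stop("missing_rate must be a scalar or a named vector", call. = FALSE)
  }
  structure(
    list(n_per_year = n_per_year, marginals = marginals, beta = beta,
         phi0 = phi0, phi1 = phi1, seed = as.integer(seed),
         missing_rate = missing_rate),
    class = "zoip_synth_config"
  )
}

#' Generate covariate records
#'
#' Draws, for each survey year, every covariate independently from its
#' year-specific marginal. The outcome column is left unset (`NA`).
#'
#' @param config A [zoip_synth_config()].
#' @return Tibble of survey records with `sanc_visits = NA`.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "zoip_synth_config"))
  lev <- sanc_levels()
  withr::with_seed(derive_seed(config$seed, 1L), {
    per_year <- purrr::map(names(.sanc_years), function(yr) {
      n <- config$n_per_year[[yr]]
      cols <- purrr::map(names(lev), function(v) {
        sample(lev[[v]], n, replace = TRUE, prob = config$marginals[[v]][[yr]])
      })
      names(cols) <- names(lev)
      tibble::as_tibble(cols) |>
        dplyr::mutate(survey_year = yr, sanc_visits = NA_integer_, .before = 1)
    })
    dplyr::bind_rows(per_year)[, .analysis_columns]
  })
}

#' Generate ZOIP outcomes for covariate records
#'
#' Builds the design matrix under the fixed coding, sets
#' `lambda_i = exp(x_i' beta)`, and draws each outcome from the ZOIP
#' mixture.
#'
#' @param records Tibble of survey records with complete covariates.
#' @param config A [zoip_synth_config()].
#' @return `records` with `sanc_visits` filled in.
#' @export
generate_outcomes <- function(records, config) {
  stopifnot(inherits(config, "zoip_synth_config"))
  tmp <- dplyr::mutate(records, sanc_visits = 0L)
  design <- build_design_matrix(tmp)
  if (length(config$beta) != ncol(design$X)) {
    stop("config beta length does not match the design width", call. = FALSE)
  }
  lambda <- exp(drop(design$X %*% config$beta))
  y <- rzoip(nrow(records), lambda, config$phi0, config$phi1,
             seed = derive_seed(config$seed, 2L))
  dplyr::mutate(records, sanc_visits = y)
}

inject_missing <- function(data, missing_rate, seed) {
  rates <- missing_rate
  fields <- setdiff(.analysis_columns, c("sanc_visits", "survey_year"))
  if (is.null(names(rates))) {
    rates <- stats::setNames(rep(rates, length(fields)), fields)
  }
  rates <- rates[rates > 0]
  if (length(rates) == 0) return(data)
  withr::with_seed(seed, {
    for (f in names(rates)) {
      hit <- stats::runif(nrow(data)) < rates[[f]]
      data[[f]][hit] <- NA
    }
  })
  data
}

#' Generate a pooled synthetic dataset
#'
#' Covariates plus ZOIP outcomes, with optional missingness injected
#' completely at random.
#'
#' @param config A [zoip_synth_config()].
#' @return Tibble of survey records in the analysis schema.
#' @export
#' @examples
#' dat <- generate_pooled_data(zoip_synth_config(n_per_year = c(50, 50, 50, 50), seed = 3))
#' nrow(dat)
generate_pooled_data <- function(config) {
  records <- generate_covariates(config)
  records <- generate_outcomes(records, config)
  inject_missing(records, config$missing_rate, derive_seed(config$seed, 3L))
}

#' Write a synthetic dataset and its truth sidecar
#'
#' Emits the analysis-ready CSV plus a JSON sidecar recording the
#' generating truth (coefficients, masses, seed, sample sizes) for
#' parameter-recovery tests.
#'
#' @param config A [zoip_synth_config()].
#' @param csv_path Destination CSV path.
#' @param sidecar_path Destination JSON path; default `csv_path` with a
#'   `.truth.json` suffix.
#' @return Invisibly, a list with `csv_path`, `sidecar_path`, and the
#'   generated tibble `data`.
#' @export
generate_pooled_dataset <- function(config, csv_path,
                                    sidecar_path = paste0(csv_path, ".truth.json")) {
  dat <- generate_pooled_data(config)
  readr::write_csv(dat, csv_path, na = "")
  truth <- list(
    beta = as.list(config$beta),
    phi0 = config$phi0,
    phi1 = config$phi1,
    seed = config$seed,
    n_per_year = as.list(config$n_per_year),
    missing_rate = config$missing_rate
  )
  jsonlite::write_json(truth, sidecar_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(csv_path = csv_path, sidecar_path = sidecar_path, data = dat))
}
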