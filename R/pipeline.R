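# Full-analysis orchestration: descriptives -> percent distributions ->
# bivariate screening -> score test -> ZOIP regression -> trend contrasts,
# with machine-readable output. Every block of the report is a plain
# tibble or scalar so the JSON serialization round-trips.

#' Run the full SANC-visits analysis
#'
#' Executes the whole pipeline on a conforming dataset: validation,
#' optional raw-schema recoding, complete-case filtering, outcome
#' descriptives, percent distributions, Kruskal-Wallis/Mann-Whitney
#' screening, the zero/one-inflation score test, the ZOIP regression with
#' mean-ratio table, and the residence-by-year trend contrasts. The trend
#' stage is skipped with a warning when fewer than two survey years are
#' present.
#'
#' @param data Data frame of survey records, or `NULL` to read `input_csv`.
#' @param input_csv Path to a CSV in the analysis (or raw) schema.
#' @param raw Is the input in the raw (pre-recode) schema?
#' @param alpha Significance threshold gating pairwise comparisons.
#' @param bonferroni Bonferroni-adjust pairwise Mann-Whitney p-values?
#' @param quiet Suppress stage messages.
#' @return Object of class `sanc_report`: list with `table1` (outcome
#'   summary), `table2` (percent distributions), `table3` (bivariate
#'   screening), `score_test`, `table4` (mean-ratio table), `fit`,
#'   `trend`, and `provenance`.
#' @export
run_full_analysis <- function(data = NULL, input_csv = NULL, raw = FALSE,
                              alpha = 0.05, bonferroni = FALSE,
                              quiet = FALSE) {
  say <- function(...) if (!quiet) rlang::inform(sprintf(...))
  if (is.null(data)) {
    if (is.null(input_csv)) stop("provide data or input_csv", call. = FALSE)
    data <- read_sanc_csv(input_csv, raw = raw, quiet = quiet)
  } else {
    if (raw) data <- recode_covariates(data)
    data <- validate_sanc_data(data, quiet = quiet)
  }
  n_in <- nrow(data)
  data <- complete_case_filter(data, quiet = quiet)
  say("stage filter: kept %d of %d records", nrow(data), n_in)

  table1 <- sanc_outcome_summary(data)
  say("stage descriptives: done")
  table2 <- purrr::map_dfr(names(sanc_levels()), function(v) {
    dplyr::mutate(percent_distribution(data, v), covariate = v, .before = 1)
  })
  table3 <- sanc_bivariate(data, alpha = alpha, bonferroni = bonferroni)
  say("stage bivariate: %d covariates screened", nrow(table3))
  st <- score_test_zero_one(data$sanc_visits)
  say("stage score test: statistic %.2f, p %.3g", st$statistic, st$p_value)

  design <- build_design_matrix(data)
  single_year <- length(unique(data$survey_year)) < 2
  X <- design$X
  if (single_year) {
    # a constant year code is collinear with the intercept
    X <- X[, setdiff(colnames(X), c("year_code", "rural_x_year")), drop = FALSE]
    rlang::warn("single survey year in data; trend stage skipped")
  }
  fit <- fit_zoip_matrix(design$y, X)
  if (!fit$converged) {
    stop("stage fit: ZOIP optimization did not converge; ",
         "inspect the design for separation or rescale", call. = FALSE)
  }
  table4 <- mean_ratio_table(fit)
  say("stage fit: loglik %.2f, phi0 %.3f, phi1 %.3f",
      fit$loglik, fit$phi0, fit$phi1)

  trend <- NULL
  if (!single_year) {
    trend <- rural_urban_trend_table(fit)
    say("stage trend: done")
  }

  structure(
    list(
      table1 = table1, table2 = table2, table3 = table3,
      score_test = tidy(st), table4 = table4, fit = fit, trend = trend,
      provenance = list(
        input = input_csv %||% "in-memory data frame",
        n_input = n_in, n_complete = nrow(data),
        alpha = alpha, bonferroni = bonferroni,
        package_version = as.character(utils::packageVersion("zoipanc"))
      )
    ),
    class = "sanc_report"
  )
}

round_df <- function(df, digits) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, digits)))
}

#' Write the report tables
#'
#' Emits `table1.csv` ... `table4.csv`, `fig1.csv`, `fig2.csv` and
#' `report.json` into a directory. Means are rounded to 2 decimals,
#' coefficients and ratios to 3; the JSON carries full precision.
#'
#' @param report A `sanc_report`.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_tables <- function(report, out_dir) {
  stopifnot(inherits(report, "sanc_report"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  readr::write_csv(round_df(report$table1, 2), path("table1.csv"))
  readr::write_csv(round_df(report$table2, 1), path("table2.csv"))
  t3 <- report$table3 |>
    dplyr::mutate(
      pairwise = purrr::map_chr(.data$pairwise, function(pw) {
        if (is.null(pw)) return("")
        paste(sprintf("%s-%s(%.4g)", pw$group1, pw$group2, pw$p_value),
              collapse = "; ")
      }),
      group_means = purrr::map_chr(.data$group_means, function(gm) {
        paste(sprintf("%s=%.2f", gm$level, gm$pooled), collapse = "; ")
      })
    )
  readr::write_csv(round_df(t3[c("covariate", "kw_statistic", "kw_df", "kw_p",
                                 "group_means", "pairwise")], 4),
                   path("table3.csv"))
  readr::write_csv(round_df(report$table4, 3), path("table4.csv"))
  if (!is.null(report$trend)) {
    readr::write_csv(round_df(report$trend$rural_vs_urban, 3), path("fig1.csv"))
    readr::write_csv(round_df(report$trend$trend_by_area, 3), path("fig2.csv"))
  }

  json <- list(
    table1 = report$table1,
    table2 = report$table2,
    table3 = report$table3[c("covariate", "kw_statistic", "kw_df", "kw_p")],
    score_test = report$score_test,
    table4 = report$table4,
    trend = if (!is.null(report$trend)) {
      list(rural_vs_urban = report$trend$rural_vs_urban,
           trend_by_area = report$trend$trend_by_area)
    },
    fit = list(loglik = report$fit$loglik, converged = report$fit$converged,
               phi0 = report$fit$phi0, phi1 = report$fit$phi1,
               n = report$fit$n, p = report$fit$p),
    provenance = report$provenance
  )
  jsonlite::write_json(json, path("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  files <- c("table1.csv", "table2.csv", "table3.csv", "table4.csv",
             if (!is.null(report$trend)) c("fig1.csv", "fig2.csv"),
             "report.json")
  invisible(vapply(files, path, character(1)))
}

#' @export
print.sanc_report <- function(x, ...) {
  cat("SANC-visits analysis report\n")
  cat(sprintf("  records: %d complete of %d input\n",
              x$provenance$n_complete, x$provenance$n_input))
  cat(sprintf("  score test: statistic %.2f (df %d), p %.3g\n",
              x$score_test$statistic, x$score_test$df, x$score_test$p.value))
  cat(sprintf("  ZOIP fit: loglik %.2f, phi0 %.4f, phi1 %.4f\n",
              x$fit$loglik, x$fit$phi0, x$fit$phi1))
  invisible(x)
}
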