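# Interaction contrasts on the Poisson-mean scale: year-specific
# rural-vs-urban mean ratios and area-specific per-year trend ratios, with
# delta-method standard errors. For a contrast vector a, the ratio is
# exp(a'beta); its log-scale SE is sqrt(a'Va) and the default 95% CI is
# computed on the log scale and exponentiated (always positive bounds); a
# symmetric-on-ratio CI is available for sensitivity.

#' Delta-method mean-ratio contrast
#'
#' @param fit A converged `zoip_fit` with a vcov.
#' @param a Named numeric contrast over (a subset of) the fit's
#'   coefficient labels; unnamed full-length vectors are also accepted.
#' @param description Optional human-readable label.
#' @param ci_scale `"log"` (default: CI computed on log ratio, then
#'   exponentiated) or `"ratio"` (symmetric on the ratio scale).
#' @return One-row tibble: `description`, `log_ratio`, `ratio`, `se`
#'   (delta-method SE of the ratio), `ci_low`, `ci_high`.
#' @export
#' @examples
#' # ratio of means for a +1 change in the year code, urban stratum
#' # contrast_mean_ratio(fit, c(year_code = 1))
contrast_mean_ratio <- function(fit, a, description = NULL,
                                ci_scale = c("log", "ratio")) {
  stopifnot(inherits(fit, "zoip_fit"))
  if (is.null(fit$vcov)) stop("fit has no vcov", call. = FALSE)
  ci_scale <- match.arg(ci_scale)
  labels <- fit$column_labels
  if (!is.null(names(a))) {
    unknown <- setdiff(names(a), labels)
    if (length(unknown) > 0) {
      stop("contrast names not in fit: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    full <- stats::setNames(numeric(length(labels)), labels)
    full[names(a)] <- a
    a <- full
  } else if (length(a) != length(labels)) {
    stop("unnamed contrast must have one entry per coefficient", call. = FALSE)
  }
  V <- fit$vcov[labels, labels, drop = FALSE]
  est <- sum(a * fit$coefficients)
  se_log <- sqrt(drop(t(a) %*% V %*% a))
  ratio <- exp(est)
  if (ci_scale == "log") {
    lo <- ratio * exp(-1.96 * se_log)
    hi <- ratio * exp(1.96 * se_log)
  } else {
    lo <- ratio - 1.96 * ratio * se_log
    hi <- ratio + 1.96 * ratio * se_log
  }
  tibble::tibble(
    description = description %||% paste0("exp(",
      paste(sprintf("%+g*%s", a[a != 0], labels[a != 0]), collapse = " "), ")"),
    log_ratio = est,
    ratio = ratio,
    se = ratio * se_log,
    ci_low = lo,
    ci_high = hi
  )
}

#' Rural/urban trend contrast tables
#'
#' Builds the two figure tables of the residence-by-year interaction
#' analysis: the year-specific rural-vs-urban mean ratio
#' `exp(beta_rural + t * beta_interaction)` for year codes t = 1..4, and
#' the per-unit-year trend ratio within each area — `exp(beta_year)` for
#' urban, `exp(beta_year + beta_interaction)` for rural.
#'
#' @param fit A `zoip_fit` containing `residence_rural`, `year_code` and
#'   `rural_x_year` coefficients.
#' @param ci_scale Passed to [contrast_mean_ratio()].
#' @return List of two tibbles, `rural_vs_urban` (one row per survey year)
#'   and `trend_by_area` (urban and rural rows), of class
#'   `zoip_trend_table`.
#' @export
rural_urban_trend_table <- function(fit, ci_scale = "log") {
  need <- c("residence_rural", "year_code", "rural_x_year")
  if (!all(need %in% fit$column_labels)) {
    stop("fit lacks required coefficients: ",
         paste(setdiff(need, fit$column_labels), collapse = ", "), call. = FALSE)
  }
  fig1 <- purrr::map_dfr(seq_along(.sanc_years), function(t) {
    dplyr::mutate(
      contrast_mean_ratio(
        fit, c(residence_rural = 1, rural_x_year = t),
        description = sprintf("rural vs urban, %s", names(.sanc_years)[t]),
        ci_scale = ci_scale),
      survey_year = names(.sanc_years)[t], year_code = t, .before = 1)
  })
  fig2 <- dplyr::bind_rows(
    dplyr::mutate(
      contrast_mean_ratio(fit, c(year_code = 1),
                          description = "per-year trend, urban",
                          ci_scale = ci_scale),
      residence = "urban", .before = 1),
    dplyr::mutate(
      contrast_mean_ratio(fit, c(year_code = 1, rural_x_year = 1),
                          description = "per-year trend, rural",
                          ci_scale = ci_scale),
      residence = "rural", .before = 1)
  )
  structure(list(rural_vs_urban = fig1, trend_by_area = fig2),
            class = "zoip_trend_table")
}

#' @export
print.zoip_trend_table <- function(x, ...) {
  cat("Rural-vs-urban mean ratio by survey year:\n")
  print(as.data.frame(x$rural_vs_urban[c("survey_year", "ratio", "ci_low", "ci_high")]),
        row.names = FALSE, digits = 3)
  cat("Per-unit-year trend ratio by area:\n")
  print(as.data.frame(x$trend_by_area[c("residence", "ratio", "ci_low", "ci_high")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' Plot the trend contrast tables
#'
#' Point-and-interval plot of the year-specific rural-vs-urban mean
#' ratios.
#'
#' @param object A `zoip_trend_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zoip_trend_table
#' @export
autoplot.zoip_trend_table <- function(object, ...) {
  ggplot2::ggplot(object$rural_vs_urban,
                  ggplot2::aes(x = .data$survey_year, y = .data$ratio)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::labs(x = "survey year", y = "rural vs urban mean ratio",
                  title = "Rural-vs-urban mean ratio of SANC visits by survey year") +
    ggplot2::theme_minimal()
}
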