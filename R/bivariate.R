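# Descriptive and unadjusted-association stage: mean +/- SD with normal
# 95% CI, percent distributions, per-group mean tables, Kruskal-Wallis
# screening and pairwise Mann-Whitney follow-up. The rank tests go through
# stats::kruskal.test / stats::wilcox.test (tie correction always on —
# visit counts are heavily tied); an exact permutation mode is available
# for two small groups.

#' Mean, SD and normal-approximation 95% CI
#'
#' @param y Numeric vector, `length(y) >= 2`.
#' @return One-row tibble: `n`, `mean`, `sd` (n-1 denominator), `ci_low`,
#'   `ci_high` (mean +/- 1.96 sd/sqrt(n)).
#' @export
mean_ci <- function(y) {
  if (length(y) < 2) stop("need at least 2 observations", call. = FALSE)
  m <- mean(y); s <- stats::sd(y); n <- length(y)
  half <- 1.96 * s / sqrt(n)
  tibble::tibble(n = n, mean = m, sd = s, ci_low = m - half, ci_high = m + half)
}

#' Outcome summary by survey year
#'
#' Mean visit count with SD and 95% CI per survey year plus the pooled
#' sample (report-table layout).
#'
#' @param data Complete-case tibble of survey records.
#' @return Tibble with one row per survey year and a final pooled row.
#' @export
sanc_outcome_summary <- function(data) {
  per_year <- data |>
    dplyr::group_by(survey_year = factor(.data$survey_year, levels = names(.sanc_years))) |>
    dplyr::reframe(mean_ci(.data$sanc_visits)) |>
    dplyr::mutate(survey_year = as.character(.data$survey_year))
  pooled <- dplyr::mutate(mean_ci(data$sanc_visits), survey_year = "pooled",
                          .before = 1)
  dplyr::bind_rows(per_year, pooled)
}

#' Percent distribution of a covariate
#'
#' Column percentages of a categorical covariate per survey year and
#' pooled; each column sums to 100 up to rounding.
#'
#' @param data Complete-case tibble of survey records.
#' @param covariate Name of a covariate listed in [sanc_levels()].
#' @param by_year Include per-year columns (default) or only the pooled one.
#' @return Tibble with a `level` column and one percentage column per
#'   survey year plus `pooled`.
#' @export
percent_distribution <- function(data, covariate, by_year = TRUE) {
  lev <- sanc_levels()
  if (!covariate %in% names(lev)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  x <- factor(data[[covariate]], levels = lev[[covariate]])
  pct <- function(f) 100 * as.numeric(table(f)) / length(f)
  out <- tibble::tibble(level = lev[[covariate]])
  if (by_year) {
    for (yr in names(.sanc_years)) {
      sel <- data$survey_year == yr
      out[[yr]] <- if (any(sel)) pct(x[sel]) else NA_real_
    }
  }
  out$pooled <- pct(x)
  out
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference
#' (`#groups - 1` df), or an exact permutation p-value for two small
#' groups.
#'
#' @param y Numeric outcome vector.
#' @param groups Group labels, same length as `y`.
#' @param method `"asymptotic"` (default) or `"permutation"` (exact
#'   enumeration; two groups of at most 10 each).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`.
#' @export
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4), c("a", "a", "b", "b")) # H = 2.4
kruskal_wallis <- function(y, groups, method = c("asymptotic", "permutation")) {
  method <- match.arg(method)
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab == 0)) stop("every group must be nonempty", call. = FALSE)
  if (stats::var(y) == 0) {
    return(tibble::tibble(statistic = 0, df = length(tab) - 1L, p_value = 1,
                          method = method))
  }
  kt <- stats::kruskal.test(y, factor(groups))
  H <- unname(kt$statistic)
  if (method == "asymptotic") {
    return(tibble::tibble(statistic = H, df = unname(kt$parameter),
                          p_value = kt$p.value, method = method))
  }
  if (length(tab) != 2 || any(tab > 10)) {
    stop("exact permutation supported for two groups of at most 10 each",
         call. = FALSE)
  }
  g1 <- names(tab)[1]
  idx <- utils::combn(length(y), tab[[g1]])
  h_of <- function(pick) {
    g <- rep(names(tab)[2], length(y)); g[pick] <- g1
    unname(stats::kruskal.test(y, factor(g))$statistic)
  }
  perm <- apply(idx, 2, h_of)
  tibble::tibble(statistic = H, df = 1L,
                 p_value = mean(perm >= H - 1e-12), method = method)
}

mw_u_statistic <- function(y1, y2) {
  r <- rank(c(y1, y2))
  sum(r[seq_along(y1)]) - length(y1) * (length(y1) + 1) / 2
}

#' Pairwise Mann-Whitney comparisons
#'
#' Two-sided Mann-Whitney U tests (tie-corrected normal approximation)
#' for every requested pair of group levels. P-values are reported
#' unadjusted to match report-table conventions; a Bonferroni column can
#' be added.
#'
#' @param y Numeric outcome vector.
#' @param groups Group labels, same length as `y`.
#' @param pairs Optional list of 2-element character vectors; defaults to
#'   all level pairs in label order.
#' @param bonferroni Add a `p_adjusted` column (Bonferroni over the
#'   reported pairs)?
#' @return Tibble: `group1`, `group2`, `U` (wins of `group1`), `p_value`,
#'   optionally `p_adjusted`.
#' @export
mann_whitney_pairwise <- function(y, groups, pairs = NULL, bonferroni = FALSE) {
  groups <- as.character(groups)
  lev <- unique(groups)
  if (is.null(pairs)) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  }
  rows <- purrr::map_dfr(pairs, function(pr) {
    y1 <- y[groups == pr[1]]
    y2 <- y[groups == pr[2]]
    if (length(y1) == 0 || length(y2) == 0) {
      stop("empty group in pair ", pr[1], "-", pr[2], call. = FALSE)
    }
    wt <- suppressWarnings(stats::wilcox.test(y1, y2, exact = FALSE,
                                              correct = FALSE))
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   U = mw_u_statistic(y1, y2), p_value = wt$p.value)
  })
  if (bonferroni) {
    rows$p_adjusted <- pmin(1, rows$p_value * nrow(rows))
  }
  rows
}

#' Mean outcome by covariate level and survey year
#'
#' @param data Complete-case tibble of survey records.
#' @param covariate Name of a covariate listed in [sanc_levels()].
#' @param by_year Include per-year columns (default) or only the pooled one.
#' @return Tibble with a `level` column, one mean column per survey year
#'   (when `by_year`), and `pooled`. Empty cells are `NA`, never 0.
#' @export
group_mean_table <- function(data, covariate, by_year = TRUE) {
  lev <- sanc_levels()
  if (!covariate %in% names(lev)) {
    stop("unknown covariate: ", covariate, call. = FALSE)
  }
  cell_mean <- function(sel) if (any(sel)) mean(data$sanc_visits[sel]) else NA_real_
  out <- tibble::tibble(level = lev[[covariate]])
  if (by_year) {
    for (yr in names(.sanc_years)) {
      out[[yr]] <- vapply(out$level, function(l)
        cell_mean(data[[covariate]] == l & data$survey_year == yr), numeric(1),
        USE.NAMES = FALSE)
    }
  }
  out$pooled <- vapply(out$level, function(l)
    cell_mean(data[[covariate]] == l), numeric(1), USE.NAMES = FALSE)
  out
}

#' Bivariate screening of all covariates
#'
#' For each covariate: pooled group means, the Kruskal-Wallis test, and —
#' when the covariate has more than two levels and the KW p-value is below
#' `alpha` — pairwise Mann-Whitney comparisons.
#'
#' @param data Complete-case tibble of survey records.
#' @param covariates Covariate names (default: all in [sanc_levels()]).
#' @param alpha Threshold gating the pairwise stage (default 0.05).
#' @param bonferroni Passed to [mann_whitney_pairwise()].
#' @return Tibble with one row per covariate: `covariate`, `kw_statistic`,
#'   `kw_df`, `kw_p`, and list-columns `group_means`, `pairwise`.
#' @export
sanc_bivariate <- function(data, covariates = names(sanc_levels()),
                           alpha = 0.05, bonferroni = FALSE) {
  purrr::map_dfr(covariates, function(v) {
    kw <- kruskal_wallis(data$sanc_visits, data[[v]])
    n_lev <- length(unique(data[[v]]))
    pw <- if (n_lev > 2 && kw$p_value < alpha) {
      mann_whitney_pairwise(data$sanc_visits, data[[v]], bonferroni = bonferroni)
    } else {
      NULL
    }
    tibble::tibble(
      covariate = v,
      kw_statistic = kw$statistic,
      kw_df = kw$df,
      kw_p = kw$p_value,
      group_means = list(group_mean_table(data, v, by_year = FALSE)),
      pairwise = list(pw)
    )
  })
}
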