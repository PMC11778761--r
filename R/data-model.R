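# Record schema, covariate recoding, complete-case filtering and the
# regression design matrix.
#
# Two CSV schemas are supported: the analysis schema (already collapsed
# levels, see sanc_levels()) and a raw schema carrying pre-recode source
# variables (5-level wealth index, media-use frequencies, three
# decision-participation indicators, five wife-beating-opinion indicators,
# 3-level pregnancy intention). Empty strings and "NA" are treated as the
# missing marker at parse time.

.analysis_columns <- c(
  "sanc_visits", "survey_year", "residence", "maternal_age", "maternal_edu",
  "paternal_edu", "wealth", "birth_order", "working", "media", "decision",
  "violence_opinion", "wanted_pregnancy", "terminated_pregnancy"
)

.raw_only_columns <- c(
  "wealth5", "media_newspaper", "media_tv", "media_radio",
  "decision_health", "decision_purchases", "decision_visits",
  "beat_argue", "beat_neglect", "beat_goout", "beat_refuse", "beat_burn",
  "wanted3"
)

.raw_levels <- list(
  wealth5 = c("poorest", "poorer", "middle", "richer", "richest"),
  media_freq = c("not_at_all", "less_than_weekly", "at_least_weekly"),
  yesno = c("yes", "no"),
  wanted3 = c("then", "later", "no_more")
)

na_normalize <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "NA")] <- NA_character_
  x
}

#' Read a SANC-visits CSV
#'
#' Reads a mother-level CSV in either the analysis schema or the raw
#' (pre-recode) schema and validates it with [validate_sanc_data()].
#'
#' @param path Path to the CSV file.
#' @param raw Logical; is the file in the raw schema (recoded on read)?
#' @param quiet Suppress per-year row-count messages.
#' @return A validated tibble of survey records.
#' @export
read_sanc_csv <- function(path, raw = FALSE, quiet = FALSE) {
  tbl <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (raw) tbl <- recode_covariates(tbl)
  validate_sanc_data(tbl, quiet = quiet)
}

#' Validate a table of survey records
#'
#' Checks the analysis schema: all required columns present, the outcome a
#' non-negative integer, every categorical field either a canonical level
#' or missing. Empty strings and `"NA"` become the missing marker; the
#' survey-year label accepts the en-dash variant of 2017-18.
#'
#' @param data Data frame in the analysis schema.
#' @param quiet Suppress the per-year row-count message.
#' @return A tibble with `sanc_visits` integer and all covariates character.
#' @export
validate_sanc_data <- function(data, quiet = FALSE) {
  missing_cols <- setdiff(.analysis_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(data)[.analysis_columns]
  out <- dplyr::mutate(out, dplyr::across(dplyr::everything(), na_normalize))
  out$survey_year <- normalize_year(out$survey_year)

  visits <- suppressWarnings(as.numeric(out$sanc_visits))
  bad <- which(!is.na(out$sanc_visits) &
                 (is.na(visits) | visits < 0 | visits != floor(visits)))
  if (length(bad) > 0) {
    stop("sanc_visits must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  out$sanc_visits <- as.integer(visits)

  lev <- sanc_levels()
  for (v in names(lev)) {
    bad <- which(!is.na(out[[v]]) & !(out[[v]] %in% lev[[v]]))
    if (length(bad) > 0) {
      stop(sprintf("unknown level '%s' in column '%s'; offending row(s): %s",
                   out[[v]][bad[1]], v,
                   paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
    }
  }
  bad <- which(!is.na(out$survey_year) & !(out$survey_year %in% names(.sanc_years)))
  if (length(bad) > 0) {
    stop("unknown survey_year label; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (!quiet) {
    counts <- table(factor(out$survey_year, levels = names(.sanc_years)))
    rlang::inform(paste0("records per survey year: ",
                         paste(names(counts), counts, sep = " = ", collapse = ", ")))
  }
  out
}

recode_one <- function(x, field, map) {
  lev <- names(map)
  bad <- which(!is.na(x) & !(x %in% lev))
  if (length(bad) > 0) {
    stop(sprintf("unknown level '%s' in raw field '%s'", x[bad[1]], field),
         call. = FALSE)
  }
  unname(map[x])
}

# Strict missing propagation for multi-indicator recodes: any missing
# source indicator makes the derived field missing (complete-case analysis
# drops the record either way, and "don't know" is treated as missing).
any_yes <- function(...) {
  ind <- cbind(...)
  out <- ifelse(rowSums(is.na(ind)) > 0, NA,
                rowSums(ind == "yes", na.rm = TRUE) > 0)
  ifelse(is.na(out), NA_character_, ifelse(out, "yes", "no"))
}

#' Recode raw survey variables to the analysis schema
#'
#' Applies the collapsing rules used throughout the package:
#' * wealth: `poorest`/`poorer` merge to `poor`, `richer`/`richest` to `rich`;
#' * media exposure: exposed if newspaper, TV or radio is used at least
#'   once a week;
#' * decision participation: yes if the mother takes part in any of the
#'   three household decisions;
#' * opinion on violence: justified if any of the five wife-beating reasons
#'   is endorsed;
#' * wanted pregnancy: `then` and `later` merge to yes.
#'
#' A missing source value propagates to the derived field. A table already
#' in the analysis schema (no raw columns present) is returned unchanged,
#' so the recode is idempotent.
#'
#' @param data Data frame in the raw schema.
#' @return Tibble in the analysis schema.
#' @export
recode_covariates <- function(data) {
  data <- tibble::as_tibble(data)
  if (!any(.raw_only_columns %in% names(data))) {
    return(data) # already analysis-coded
  }
  missing_cols <- setdiff(.raw_only_columns, names(data))
  if (length(missing_cols) > 0) {
    stop("raw schema missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- dplyr::mutate(
    data,
    dplyr::across(dplyr::all_of(.raw_only_columns), na_normalize)
  )

  wealth_map <- c(poorest = "poor", poorer = "poor", middle = "middle",
                  richer = "rich", richest = "rich")
  for (mcol in c("media_newspaper", "media_tv", "media_radio")) {
    recode_one(data[[mcol]], mcol,
               stats::setNames(.raw_levels$media_freq, .raw_levels$media_freq))
  }
  for (ycol in c("decision_health", "decision_purchases", "decision_visits",
                 "beat_argue", "beat_neglect", "beat_goout", "beat_refuse",
                 "beat_burn")) {
    recode_one(data[[ycol]], ycol, c(yes = "yes", no = "no"))
  }

  media_weekly <- function(x) ifelse(is.na(x), NA, x == "at_least_weekly")
  mw <- cbind(media_weekly(data$media_newspaper),
              media_weekly(data$media_tv),
              media_weekly(data$media_radio))
  media <- ifelse(rowSums(is.na(mw)) > 0, NA, rowSums(mw, na.rm = TRUE) > 0)

  out <- dplyr::mutate(
    data,
    wealth = recode_one(.data$wealth5, "wealth5", wealth_map),
    media = ifelse(is.na(media), NA_character_,
                   ifelse(media, "exposed", "non_exposed")),
    decision = any_yes(.data$decision_health, .data$decision_purchases,
                       .data$decision_visits),
    violence_opinion = dplyr::case_when(
      is.na(any_yes(.data$beat_argue, .data$beat_neglect, .data$beat_goout,
                    .data$beat_refuse, .data$beat_burn)) ~ NA_character_,
      any_yes(.data$beat_argue, .data$beat_neglect, .data$beat_goout,
              .data$beat_refuse, .data$beat_burn) == "yes" ~ "justified",
      TRUE ~ "non_justified"
    ),
    wanted_pregnancy = recode_one(.data$wanted3, "wanted3",
                                  c(then = "yes", later = "yes", no_more = "no"))
  )
  dplyr::select(out, -dplyr::all_of(.raw_only_columns))
}

#' Drop records with any missing value
#'
#' Complete-case filter over the outcome and all covariates; input order is
#' preserved. The number of dropped rows is attached as attribute
#' `n_dropped` and returned invisibly in messages.
#'
#' @param data Validated tibble of survey records.
#' @param quiet Suppress the dropped-row message.
#' @return The kept rows, with attribute `n_dropped`.
#' @export
complete_case_filter <- function(data, quiet = FALSE) {
  keep <- stats::complete.cases(data[.analysis_columns])
  out <- data[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  if (!quiet && sum(!keep) > 0) {
    rlang::inform(sprintf("complete-case filter dropped %d of %d records",
                          sum(!keep), nrow(data)))
  }
  out
}

#' Build the regression design matrix
#'
#' One-hot codes every covariate against its reference level (the first
#' entry of [sanc_levels()]), maps the survey year to its 1-4 code, and
#' appends the rural-by-year interaction column. Column order is fixed:
#' intercept, 19 dummies, `year_code`, `rural_x_year` (p = 22).
#'
#' @param data Complete-case tibble of survey records.
#' @return Object of class `zoip_design`: list with `y`, `X`,
#'   `column_labels`, `reference_map`, `year_code`, `n`, `p`.
#' @export
build_design_matrix <- function(data) {
  if (nrow(data) == 0) stop("no records to build a design matrix from", call. = FALSE)
  if (anyNA(data[.analysis_columns])) {
    stop("design matrix requires complete cases; run complete_case_filter()",
         call. = FALSE)
  }
  lev <- sanc_levels()
  single <- names(lev)[vapply(names(lev), function(v)
    length(unique(data[[v]])) == 1L, logical(1))]
  if (length(single) > 0) {
    stop("covariate(s) with a single observed level: ",
         paste(single, collapse = ", "), call. = FALSE)
  }

  n <- nrow(data)
  year_code <- unname(.sanc_years[data$survey_year])
  rural <- as.numeric(data$residence == "rural")

  dummy <- function(v, l) as.numeric(data[[v]] == l)
  X <- cbind(
    "(Intercept)"      = rep(1, n),
    residence_rural    = rural,
    age_20_34          = dummy("maternal_age", "20-34"),
    age_over34         = dummy("maternal_age", ">34"),
    medu_primary       = dummy("maternal_edu", "primary"),
    medu_secondary     = dummy("maternal_edu", "secondary"),
    medu_higher        = dummy("maternal_edu", "higher"),
    pedu_primary       = dummy("paternal_edu", "primary"),
    pedu_secondary     = dummy("paternal_edu", "secondary"),
    pedu_higher        = dummy("paternal_edu", "higher"),
    wealth_middle      = dummy("wealth", "middle"),
    wealth_rich        = dummy("wealth", "rich"),
    birth_second_third = dummy("birth_order", "second_third"),
    birth_above_third  = dummy("birth_order", "above_third"),
    working_working    = dummy("working", "working"),
    media_exposed      = dummy("media", "exposed"),
    decision_yes       = dummy("decision", "yes"),
    violence_justified = dummy("violence_opinion", "justified"),
    wanted_yes         = dummy("wanted_pregnancy", "yes"),
    terminated_yes     = dummy("terminated_pregnancy", "yes"),
    year_code          = year_code,
    rural_x_year       = year_code * rural
  )
  stopifnot(identical(colnames(X), .design_columns))
  structure(
    list(
      y = data$sanc_visits,
      X = X,
      column_labels = .design_columns,
      reference_map = vapply(lev, `[`, character(1), 1),
      year_code = year_code,
      n = n,
      p = ncol(X)
    ),
    class = "zoip_design"
  )
}
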