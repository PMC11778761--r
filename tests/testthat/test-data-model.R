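# Schema validation, recoding rules, complete-case filter, design matrix.

make_raw <- function(n = 1) {
  tibble::tibble(
    sanc_visits = rep("2", n), survey_year = rep("2011", n),
    residence = "urban", maternal_age = "<20", maternal_edu = "none",
    paternal_edu = "none", birth_order = "first", working = "non_working",
    terminated_pregnancy = "no",
    wealth5 = "middle",
    media_newspaper = "not_at_all", media_tv = "less_than_weekly",
    media_radio = "less_than_weekly",
    decision_health = "no", decision_purchases = "no", decision_visits = "no",
    beat_argue = "no", beat_neglect = "no", beat_goout = "no",
    beat_refuse = "no", beat_burn = "no",
    wanted3 = "then"
  )
}

test_that("recode collapses source levels by the documented rules", {
  raw <- make_raw(6)
  raw$wealth5 <- c("poorest", "poorer", "middle", "richer", "richest", "middle")
  raw$media_tv[2] <- "at_least_weekly"
  raw$decision_health[3] <- "yes"
  raw$beat_burn[4] <- "yes"
  raw$wanted3 <- c("then", "later", "no_more", "then", "then", "then")
  rec <- recode_covariates(raw)
  expect_equal(rec$wealth, c("poor", "poor", "middle", "rich", "rich", "middle"))
  expect_equal(rec$media[1:2], c("non_exposed", "exposed"))
  expect_equal(rec$decision[c(1, 3)], c("no", "yes"))
  # (no, no, no, yes on any single indicator) endorses violence
  expect_equal(rec$violence_opinion[c(1, 4)], c("non_justified", "justified"))
  expect_equal(rec$wanted_pregnancy[1:3], c("yes", "yes", "no"))
  expect_false(any(c(
    "wealth5", "media_tv", "decision_health", "beat_burn", "wanted3"
  ) %in% names(rec)))
})

test_that("missing source values propagate to derived fields", {
  raw <- make_raw(3)
  raw$wealth5[1] <- NA
  raw$media_tv[2] <- ""
  raw$beat_argue[3] <- "NA"
  rec <- recode_covariates(raw)
  expect_true(is.na(rec$wealth[1]))
  expect_true(is.na(rec$media[2]))
  expect_true(is.na(rec$violence_opinion[3]))
})

test_that("recode is idempotent and rejects unknown source levels", {
  rec <- recode_covariates(make_raw(4))
  expect_identical(recode_covariates(rec), rec)
  raw <- make_raw(2)
  raw$wealth5[2] <- "wealthy"
  expect_error(recode_covariates(raw), "wealth5")
})

test_that("validation enforces the analysis schema", {
  rec <- make_records(10)
  expect_silent(out <- validate_sanc_data(rec, quiet = TRUE))
  expect_equal(nrow(out), 10)
  expect_type(out$sanc_visits, "integer")

  expect_error(validate_sanc_data(rec[setdiff(names(rec), "sanc_visits")]),
               "sanc_visits")
  bad <- rec; bad$sanc_visits[3] <- 3.5
  expect_error(validate_sanc_data(bad, quiet = TRUE), "non-negative integer")
  bad <- rec; bad$wealth[2] <- "affluent"
  expect_error(validate_sanc_data(bad, quiet = TRUE), "wealth")
})

test_that("missing markers and year spellings normalize at parse time", {
  rec <- make_records(4)
  rec$wealth[1] <- ""
  rec$media[2] <- "NA"
  rec$survey_year <- c("2011", "2017–18", "2017-18", "2022")
  out <- validate_sanc_data(rec, quiet = TRUE)
  expect_true(is.na(out$wealth[1]))
  expect_true(is.na(out$media[2]))
  expect_equal(out$survey_year[2], "2017-18")
})

test_that("complete-case filter keeps exactly the fully observed rows in order", {
  rec <- make_records(5)
  rec$sanc_visits <- 1:5
  rec$wealth[c(2, 4)] <- NA
  kept <- complete_case_filter(rec, quiet = TRUE)
  expect_equal(nrow(kept), 3)
  expect_equal(attr(kept, "n_dropped"), 2)
  expect_equal(kept$sanc_visits, c(1L, 3L, 5L)) # order preserved

  full <- make_records(7)
  kept2 <- complete_case_filter(full, quiet = TRUE)
  expect_equal(nrow(kept2), 7)
  expect_equal(attr(kept2, "n_dropped"), 0)
})

test_that("design matrix uses reference coding, year codes and the interaction", {
  rec <- make_records(2)
  rec$survey_year <- c("2011", "2022")
  rec$residence <- c("urban", "rural")
  # need both levels somewhere for every covariate? only residence varies here
  d <- build_design_matrix(dplyr::bind_rows(rec, local({
    r <- make_records(12)
    lev <- sanc_levels()
    for (v in names(lev)) r[[v]] <- rep(lev[[v]], length.out = 12)
    r$survey_year <- rep(names(sanc_year_codes()), 3)
    r
  })))
  expect_equal(d$p, 22L)
  expect_equal(unname(d$X[, 1]), rep(1, d$n))
  # all-reference 2011 urban row: dummies 0, year 1, interaction 0
  expect_equal(unname(d$X[1, -1]), c(rep(0, 19), 1, 0))
  # rural 2022 row: interaction = 4 * 1
  expect_equal(unname(d$X[2, "rural_x_year"]), 4)
  expect_equal(unname(d$X[2, "year_code"]), 4)
})

test_that("dummy blocks are exclusive one-hot encodings", {
  dat <- small_data(seed = 6, n_per_year = c(60, 60, 60, 60))
  d <- build_design_matrix(dat)
  blocks <- list(c("age_20_34", "age_over34"),
                 c("medu_primary", "medu_secondary", "medu_higher"),
                 c("wealth_middle", "wealth_rich"),
                 c("birth_second_third", "birth_above_third"))
  for (b in blocks) {
    s <- rowSums(d$X[, b, drop = FALSE])
    expect_true(all(s %in% c(0, 1)))
  }
  # rows differing only in maternal_edu differ in exactly the two edu dummies
  r2 <- dat[1, ][c(1, 1), ]
  r2$maternal_edu <- c("primary", "higher")
  base <- dat; base$maternal_edu <- rep(sanc_levels()$maternal_edu, length.out = nrow(base))
  dd <- build_design_matrix(dplyr::bind_rows(r2, base))
  diffcols <- which(dd$X[1, ] != dd$X[2, ])
  expect_setequal(colnames(dd$X)[diffcols], c("medu_primary", "medu_higher"))
})

test_that("degenerate designs are reported, not silently dropped", {
  expect_error(build_design_matrix(make_records(0)), "no records")
  rec <- make_records(30) # every covariate single-level
  expect_error(build_design_matrix(rec), "single observed level")
  rec_na <- small_data(seed = 8, n_per_year = c(30, 30, 30, 30))
  rec_na$wealth[1] <- NA
  expect_error(build_design_matrix(rec_na), "complete cases")
})

test_that("CSV round trip preserves records in both schemas", {
  dat <- small_data(seed = 10, n_per_year = c(40, 40, 40, 40))
  f <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(dat, f)
  back <- read_sanc_csv(f, quiet = TRUE)
  expect_equal(as.data.frame(back), as.data.frame(dat))

  raw <- make_raw(3)
  fr <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(raw, fr)
  back_raw <- read_sanc_csv(fr, raw = TRUE, quiet = TRUE)
  expect_equal(back_raw$wealth, rep("middle", 3))
})
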