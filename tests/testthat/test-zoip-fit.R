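# Maximum-likelihood fitting: oracle equivalences, initialization,
# standard errors, effect table, simulation calibration.

test_that("restricted fit with both masses at zero matches the Poisson GLM", {
  set.seed(5)
  n <- 500
  x <- rbinom(n, 1, 0.5); z <- rnorm(n)
  X <- cbind("(Intercept)" = 1, x = x, z = z)
  y <- rpois(n, exp(0.3 + 0.5 * x - 0.2 * z))
  fr <- fit_zoip_matrix(y, X, inflation = "none")
  g <- stats::glm(y ~ x + z, family = stats::poisson())
  expect_true(fr$converged)
  expect_lt(max(abs(coef(fr) - coef(g))), 1e-6)
  expect_equal(fr$loglik, as.numeric(logLik(g)), tolerance = 1e-10)
})

test_that("intercept-only MLE matches a brute-force grid search", {
  y <- c(0L, 0L, 0L, 1L, 1L, 2L, 3L)
  fit <- suppressWarnings(
    fit_zoip_matrix(y, matrix(1, 7, 1, dimnames = list(NULL, "(Intercept)")),
                    compute_vcov = FALSE)
  )
  ll <- function(lam, p0, p1) sum(dzoip(y, lam, p0, p1, log = TRUE))
  # coarse grid, then a 1e-3 refinement around the coarse optimum
  best <- c(-Inf, NA, NA, NA)
  for (lam in seq(0.05, 3, by = 0.05)) {
    for (p0 in seq(0, 0.7, by = 0.02)) {
      for (p1 in seq(0, 0.5, by = 0.02)) {
        if (p0 + p1 < 0.99) {
          v <- ll(lam, p0, p1)
          if (v > best[1]) best <- c(v, lam, p0, p1)
        }
      }
    }
  }
  for (lam in seq(max(0.001, best[2] - 0.06), best[2] + 0.06, by = 0.001)) {
    for (p0 in seq(max(0, best[3] - 0.025), min(0.99, best[3] + 0.025), by = 0.001)) {
      for (p1 in seq(max(0, best[4] - 0.025), min(0.99, best[4] + 0.025), by = 0.001)) {
        if (p0 + p1 < 0.999) {
          v <- ll(lam, p0, p1)
          if (v > best[1]) best <- c(v, lam, p0, p1)
        }
      }
    }
  }
  expect_equal(exp(coef(fit)[[1]]), best[2], tolerance = 2e-3)
  expect_equal(fit$phi0, best[3], tolerance = 2e-3)
  expect_equal(fit$phi1, best[4], tolerance = 2e-3)
  # phi1 maximizes on the simplex boundary here, which the logit
  # parameterization approaches asymptotically; allow that sliver
  expect_gte(fit$loglik, best[1] - 1e-5)
})

test_that("initial values follow the Poisson-GLM-plus-marginal-masses recipe", {
  # Poisson data: mass starts end near the simplex floor
  y <- rpois(4000, 2); y <- pmax(y, 0L)
  X <- matrix(1, length(y), 1)
  init <- zoip_init(y, X)
  expect_equal(init$beta, log(mean(y)), tolerance = 1e-6)
  expect_lte(init$phi0, 0.02)
  expect_lte(init$phi1, 0.02)
  # zero-heavy data push phi0 up
  yz <- c(rep(0L, 80), rep(2L, 20))
  init_z <- suppressWarnings(zoip_init(yz, matrix(1, 100, 1)))
  expect_gt(init_z$phi0, 0.3)
})

test_that("ZOIP log-likelihood never falls below the nested Poisson fit", {
  dat <- small_data(seed = 13, n_per_year = c(150, 100, 100, 100))
  fit_full <- fit_zoip(dat, compute_vcov = FALSE)
  fit_pois <- fit_zoip(dat, inflation = "none", compute_vcov = FALSE)
  expect_gte(fit_full$loglik, fit_pois$loglik)
  expect_lt(fit_full$gradient_norm, 1e-5)
})

test_that("five seeded random starts reach the same maximum", {
  dat <- small_data(seed = 17, n_per_year = c(250, 250, 250, 250))
  design <- build_design_matrix(dat)
  base <- fit_zoip_matrix(design$y, design$X, compute_vcov = FALSE)
  lls <- vapply(1:5, function(s) {
    init <- withr::with_seed(s, list(
      beta = rnorm(ncol(design$X), 0, 0.3),
      phi0 = runif(1, 0.05, 0.4), phi1 = runif(1, 0.01, 0.2)
    ))
    fit_zoip_matrix(design$y, design$X, init = init, compute_vcov = FALSE)$loglik
  }, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-4)
  expect_lt(abs(base$loglik - max(lls)), 1e-4)
})

test_that("observed-information SE matches the Poisson closed form", {
  set.seed(31)
  y <- rpois(20000, 3)
  fit <- fit_zoip_matrix(y, matrix(1, length(y), 1), inflation = "none")
  # Fisher information for log-mean Poisson: n * ybar
  expect_equal(sqrt(diag(fit$vcov))[[1]], 1 / sqrt(length(y) * mean(y)),
               tolerance = 0.01)
})

test_that("vcov is symmetric with nonnegative diagonal and labelled", {
  dat <- small_data(seed = 23, n_per_year = c(200, 150, 150, 150))
  fit <- fit_zoip(dat)
  expect_true(isSymmetric(fit$vcov))
  expect_true(all(diag(fit$vcov) >= 0))
  expect_equal(rownames(fit$vcov), c(fit$column_labels, "phi0", "phi1"))
})

test_that("reported SEs are calibrated and Wald intervals cover", {
  truth_b <- c(0.6, -0.4, 0.08, 0.1)
  phi0 <- 0.172; phi1 <- 0.011
  res <- t(vapply(1:150, function(seed) {
    withr::with_seed(seed, {
      n <- 2000
      rural <- rbinom(n, 1, 0.67)
      yr <- sample(1:4, n, replace = TRUE)
      X <- cbind("(Intercept)" = 1, rural = rural, year = yr,
                 rural_x_year = rural * yr)
      y <- rzoip(n, exp(drop(X %*% truth_b)), phi0, phi1)
      fit <- suppressWarnings(fit_zoip_matrix(y, X))
      c(coef(fit), fit$phi0, fit$phi1, sqrt(diag(fit$vcov)))
    })
  }, numeric(12)))
  est <- res[, 1:6]; se <- res[, 7:12]
  truth <- c(truth_b, phi0, phi1)
  # 95% Wald coverage for each regression coefficient
  for (j in 1:4) {
    cov_j <- mean(abs(est[, j] - truth[j]) <= 1.96 * se[, j])
    expect_gte(cov_j, 0.90)
    expect_lte(cov_j, 0.99)
  }
  # mean reported SE within 15% of the Monte-Carlo SD (coefficients and phi0)
  for (j in 1:5) {
    expect_lt(abs(mean(se[, j]) / sd(est[, j]) - 1), 0.15)
  }
})

test_that("mean-ratio table exponentiates coefficients and flags masses", {
  fit <- make_fit(c("(Intercept)" = 0.1, residence_rural = -0.523,
                    medu_higher = 0.618))
  tab <- mean_ratio_table(fit)
  expect_equal(round(tab$mean_ratio[tab$term == "residence_rural"], 3), 0.593)
  expect_equal(round(tab$mean_ratio[tab$term == "medu_higher"], 3), 1.855)
  expect_true(all(is.na(tab$mean_ratio[tab$term %in% c("phi0", "phi1")])))
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
  zero_fit <- make_fit(c("(Intercept)" = 0))
  expect_equal(mean_ratio_table(zero_fit)$mean_ratio[1], 1)
})

test_that("tidy and glance expose broom-shaped summaries", {
  dat <- small_data(seed = 29, n_per_year = c(150, 150, 150, 150))
  fit <- fit_zoip(dat)
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std.error", "p.value",
                    "mean.ratio", "conf.low", "conf.high") %in% names(td)))
  expect_equal(nrow(td), 24) # 22 coefficients + 2 masses
  expect_equal(td$mean.ratio[1:22], exp(td$estimate[1:22]))
  gl <- glance(fit)
  expect_equal(gl$nobs, nrow(dat))
  expect_true(gl$converged)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("non-convergence and boundary estimates are flagged, not hidden", {
  y <- rpois(300, 2)
  X <- matrix(1, 300, 1)
  slow <- suppressWarnings(
    fit_zoip_matrix(y, X, control = list(maxit = 1, grad_tol = 1e-12),
                    compute_vcov = FALSE)
  )
  expect_false(slow$converged)
  # a sample with no ones drives phi1 onto the boundary
  yb <- c(rep(0L, 200), rep(3L, 100), rep(5L, 50))
  Xb <- matrix(1, length(yb), 1)
  expect_warning(fb <- fit_zoip_matrix(yb, Xb, compute_vcov = FALSE),
                 "unreliable")
  expect_true(fb$boundary)
  expect_lt(fb$phi1, 1e-6)
})
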