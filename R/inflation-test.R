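# Partial score test for simultaneous inflation at zero and one.
#
# Null model: plain Poisson(lambda), lambda estimated by its MLE ybar.
# The score of the two mass parameters of the ZOIP mixture, evaluated at
# the null (phi0 = phi1 = 0), is
#   U = ( sum[ 1{y=0}/p0(lam) - 1 ],  sum[ 1{y=1}/p1(lam) - 1 ] )
# with p_j the Poisson pmf at j. Estimating lambda removes one direction
# of variability; the efficient covariance of U is the Schur complement of
# the Fisher information, per observation
#   V11 = (1 - p0)/p0 - lambda
#   V12 = -lambda
#   V22 = (1 - p1)/p1 - (1 - lambda)^2 / lambda
# The statistic U' (nV)^{-1} U is referred to chi-square with 2 degrees of
# freedom (k - 1 with k = 3 parameters). Calibration of this construction
# is validated against a parametric bootstrap in the test-suite rather
# than assumed.

score_statistic <- function(y) {
  n <- length(y)
  lam <- mean(y)
  p0 <- exp(-lam)
  p1 <- lam * exp(-lam)
  U <- c(sum((y == 0) / p0 - 1), sum((y == 1) / p1 - 1))
  V <- n * matrix(c((1 - p0) / p0 - lam, -lam,
                    -lam, (1 - p1) / p1 - (1 - lam)^2 / lam), 2, 2)
  if (abs(det(V)) < .Machine$double.eps * max(abs(V))^2) {
    stop("efficient score covariance is singular", call. = FALSE)
  }
  drop(crossprod(U, solve(V, U)))
}

#' Partial score test for simultaneous zero and one inflation
#'
#' Tests the plain-Poisson null against a mixture with structural zeros
#' and ones, without covariates. The statistic is referred to a chi-square
#' distribution with 2 degrees of freedom.
#'
#' @param y Non-negative integer count vector, `length(y) >= 30`.
#' @return Object of class `zoip_score_test`: list with `statistic`, `df`,
#'   `p_value`, `n`, `lambda_null`.
#' @export
#' @examples
#' y <- rzoip(500, lambda = 2, phi0 = 0.25, phi1 = 0.05, seed = 1)
#' score_test_zero_one(y)
score_test_zero_one <- function(y) {
  if (length(y) < 30) stop("score test needs at least 30 observations", call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) {
    stop("y must be non-negative integers", call. = FALSE)
  }
  if (mean(y) == 0) stop("degenerate all-zero sample", call. = FALSE)
  stat <- score_statistic(y)
  structure(
    list(
      statistic = stat,
      df = 2L,
      p_value = stats::pchisq(stat, df = 2, lower.tail = FALSE),
      n = length(y),
      lambda_null = mean(y)
    ),
    class = "zoip_score_test"
  )
}

#' Parametric-bootstrap p-value for the score test
#'
#' Simulates `n_boot` Poisson samples at the null MLE, recomputes the
#' statistic on each, and returns the empirical upper-tail proportion.
#' Used to validate the chi-square(2) calibration of
#' [score_test_zero_one()].
#'
#' @param y Observed count vector.
#' @param n_boot Number of bootstrap replicates (at least 200).
#' @param seed Integer seed for the bootstrap draws.
#' @return List with `p_value` (bootstrap), `statistic`, `n_boot`.
#' @export
bootstrap_null_pvalue <- function(y, n_boot = 500, seed = 1) {
  if (n_boot < 200) stop("n_boot must be at least 200", call. = FALSE)
  obs <- score_statistic(y)
  lam <- mean(y)
  n <- length(y)
  stats_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) score_statistic(stats::rpois(n, lam)),
           numeric(1))
  })
  list(p_value = mean(stats_boot >= obs), statistic = obs, n_boot = n_boot)
}

#' @export
print.zoip_score_test <- function(x, ...) {
  cat(sprintf(
    "Partial score test for zero/one inflation: statistic = %.3f, df = %d, p %s\n",
    x$statistic, x$df,
    if (x$p_value < 0.001) "< 0.001" else sprintf("= %.4f", x$p_value)))
  invisible(x)
}

#' @method tidy zoip_score_test
#' @export
tidy.zoip_score_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p.value = x$p_value,
                 nobs = x$n, lambda.null = x$lambda_null)
}
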