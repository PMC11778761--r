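# Zero-and-one-inflated Poisson (ZOIP) distribution.
#
# Three-component mixture: a point mass at 0 (weight phi0), a point mass at
# 1 (weight phi1), and Poisson(lambda) (weight phi2 = 1 - phi0 - phi1).
# The pmf is
#   P(Y = 0) = phi0 + phi2 * exp(-lambda)
#   P(Y = 1) = phi1 + phi2 * lambda * exp(-lambda)
#   P(Y = y) = phi2 * lambda^y * exp(-lambda) / y!,   y > 1.
# Log-space evaluation goes through log-sum-exp at y in {0, 1} and the
# log-gamma function for the factorial, so large lambda and counts in the
# hundreds do not underflow.

check_masses <- function(phi0, phi1, allow_boundary = FALSE) {
  if (any(!is.finite(phi0)) || any(!is.finite(phi1)) ||
      any(phi0 < 0) || any(phi1 < 0)) {
    stop("inflation masses must be finite and non-negative", call. = FALSE)
  }
  lim_ok <- if (allow_boundary) phi0 + phi1 <= 1 else phi0 + phi1 < 1
  if (any(!lim_ok)) {
    stop("inflation masses must satisfy phi0 + phi1 < 1", call. = FALSE)
  }
  invisible(TRUE)
}

# log(exp(a) + exp(b)) elementwise, tolerating -Inf.
log_add_exp <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

#' ZOIP probability mass function
#'
#' Probability mass function of the zero-and-one-inflated Poisson
#' distribution. Vectorized over `x` and `lambda`.
#'
#' @param x Vector of non-negative integer counts.
#' @param lambda Positive Poisson mean(s) of the count component.
#' @param phi0 Probability mass of structural zeros.
#' @param phi1 Probability mass of structural ones.
#' @param log Logical; return the log pmf?
#' @return Numeric vector of (log) probabilities.
#' @export
#' @examples
#' dzoip(0:4, lambda = 2, phi0 = 0.1, phi1 = 0.2)
dzoip <- function(x, lambda, phi0 = 0, phi1 = 0, log = FALSE) {
  check_masses(phi0, phi1, allow_boundary = TRUE)
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  if (any(x < 0) || any(x != floor(x))) {
    stop("x must be non-negative integers", call. = FALSE)
  }
  n <- max(length(x), length(lambda))
  x <- rep_len(x, n)
  lambda <- rep_len(lambda, n)
  phi2 <- 1 - phi0 - phi1
  lphi0 <- if (phi0 > 0) base::log(phi0) else -Inf
  lphi1 <- if (phi1 > 0) base::log(phi1) else -Inf
  lphi2 <- if (phi2 > 0) base::log(phi2) else -Inf

  lp <- lphi2 + x * base::log(lambda) - lambda - lgamma(x + 1)
  lp[x == 0] <- log_add_exp(lphi0, lphi2 - lambda[x == 0])
  i1 <- x == 1
  lp[i1] <- log_add_exp(lphi1, lphi2 + base::log(lambda[i1]) - lambda[i1])
  if (log) lp else exp(lp)
}

#' ZOIP mean
#'
#' Expectation of the ZOIP mixture: structural zeros contribute nothing,
#' structural ones contribute `phi1`, and the Poisson component contributes
#' `phi2 * lambda`.
#'
#' @inheritParams dzoip
#' @return Numeric vector `phi1 + (1 - phi0 - phi1) * lambda`.
#' @export
#' @examples
#' zoip_mean(2, phi0 = 0.1, phi1 = 0.2) # 1.6
zoip_mean <- function(lambda, phi0 = 0, phi1 = 0) {
  check_masses(phi0, phi1, allow_boundary = TRUE)
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  phi1 + (1 - phi0 - phi1) * lambda
}

#' Sample from the ZOIP distribution
#'
#' Draws `n` counts: with probability `phi0` a structural zero, with
#' probability `phi1` a structural one, otherwise a Poisson(`lambda`) draw.
#'
#' @param n Number of draws.
#' @param lambda Poisson mean(s), recycled to length `n`.
#' @inheritParams dzoip
#' @param seed Optional integer; when given, draws are made in a temporary
#'   RNG state seeded with it, so the call is reproducible and leaves the
#'   global RNG untouched.
#' @return Integer vector of length `n`.
#' @export
#' @examples
#' rzoip(10, lambda = 2, phi0 = 0.3, seed = 1)
rzoip <- function(n, lambda, phi0 = 0, phi1 = 0, seed = NULL) {
  check_masses(phi0, phi1, allow_boundary = TRUE)
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (any(lambda <= 0)) stop("lambda must be positive", call. = FALSE)
  lambda <- rep_len(lambda, n)
  draw <- function() {
    u <- stats::runif(n)
    y <- stats::rpois(n, lambda)
    y[u < phi0] <- 0L
    y[u >= phi0 & u < phi0 + phi1] <- 1L
    as.integer(y)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' ZOIP regression log-likelihood
#'
#' Log-likelihood of the ZOIP regression with log link
#' `lambda_i = exp(x_i' beta)`: the sum over observations of three blocks
#' (contributions of the zeros, the ones, and the counts above one), equal
#' to the sum of [dzoip()] log-pmfs.
#'
#' @param beta Numeric coefficient vector, length `ncol(X)`.
#' @param phi0,phi1 Inflation masses.
#' @param y Non-negative integer outcome vector.
#' @param X Design matrix with rows matching `y`.
#' @return Scalar log-likelihood.
#' @export
zoip_loglik <- function(beta, phi0, phi1, y, X) {
  if (length(beta) != ncol(X)) stop("beta length must equal ncol(X)", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  eta <- drop(X %*% beta)
  if (any(!is.finite(exp(eta)))) {
    stop("linear predictor overflows exp(); check the design scaling", call. = FALSE)
  }
  sum(dzoip(y, exp(eta), phi0, phi1, log = TRUE))
}

# Overflow-tolerant variant for use inside optimization: an overflowing or
# underflowing linear predictor yields -Inf instead of an error, so a line
# search can back off from a wild step.
zoip_loglik_safe <- function(beta, phi0, phi1, y, X) {
  eta <- drop(X %*% beta)
  lam <- pmax(exp(eta), 1e-300)
  ll <- sum(dzoip(y, lam, phi0, phi1, log = TRUE))
  if (is.nan(ll)) -Inf else ll
}
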