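# Maximum-likelihood fitting of the ZOIP regression.
#
# The likelihood is maximized over an unconstrained parameterization:
# beta free, and the inflation masses through a multinomial-logit
# transform phi_j = exp(gamma_j) / (1 + exp(gamma_0) + exp(gamma_1)),
# which keeps (phi0, phi1) strictly inside the probability simplex however
# far the optimizer wanders. Restricted modes fix either or both masses at
# zero (the "none" mode is exactly a Poisson GLM and serves as an oracle
# anchor in the tests). Standard errors come from the observed information:
# the Hessian of the log-likelihood at the MLE on the unconstrained scale
# (numDeriv applied to the analytic gradient), inverted and mapped to the
# natural scale with the transform Jacobian.

phi_from_gamma <- function(gamma) {
  m <- max(0, gamma) # softmax shift so extreme gamma cannot overflow
  e <- exp(gamma - m)
  denom <- exp(-m) + sum(e)
  c(phi0 = e[1] / denom, phi1 = e[2] / denom)
}

gamma_from_phi <- function(phi0, phi1) {
  phi2 <- 1 - phi0 - phi1
  c(log(phi0 / phi2), log(phi1 / phi2))
}

# d(phi0, phi1) / d(gamma0, gamma1), symmetric 2x2
phi_jacobian <- function(phi0, phi1) {
  matrix(c(phi0 * (1 - phi0), -phi0 * phi1,
           -phi0 * phi1, phi1 * (1 - phi1)), 2, 2)
}

# Split an unconstrained parameter vector according to the inflation mode.
split_theta <- function(theta, p, mode) {
  beta <- theta[seq_len(p)]
  rest <- theta[-seq_len(p)]
  switch(mode,
    both = {
      phi <- phi_from_gamma(rest)
      list(beta = beta, phi0 = phi[[1]], phi1 = phi[[2]])
    },
    zero = list(beta = beta, phi0 = stats::plogis(rest[1]), phi1 = 0),
    one  = list(beta = beta, phi0 = 0, phi1 = stats::plogis(rest[1])),
    none = list(beta = beta, phi0 = 0, phi1 = 0)
  )
}

zoip_nll <- function(theta, y, X, mode) {
  par <- split_theta(theta, ncol(X), mode)
  -zoip_loglik_safe(par$beta, par$phi0, par$phi1, y, X)
}

# Analytic gradient of the negative log-likelihood on the unconstrained
# scale. Per-observation natural-scale pieces:
#   y = 0: d/deta = -w0*lam,      w0 = phi2 e^{-lam} / (phi0 + phi2 e^{-lam})
#   y = 1: d/deta = w1*(1 - lam), w1 = phi2 lam e^{-lam} / (phi1 + phi2 lam e^{-lam})
#   y > 1: d/deta = y - lam
# with matching derivatives in (phi0, phi1), chained through the logit
# Jacobian for the free masses.
zoip_nll_grad <- function(theta, y, X, mode) {
  p <- ncol(X)
  par <- split_theta(theta, p, mode)
  beta <- par$beta; phi0 <- par$phi0; phi1 <- par$phi1
  phi2 <- 1 - phi0 - phi1
  lam <- exp(drop(X %*% beta))
  e <- exp(-lam)

  i0 <- y == 0; i1 <- y == 1; i2 <- y > 1
  deta <- numeric(length(y))
  dphi0 <- numeric(length(y))
  dphi1 <- numeric(length(y))

  if (any(i0)) {
    l0 <- lam[i0]
    w0 <- if (phi0 == 0) rep(1, sum(i0)) else
      1 / (1 + exp(log(phi0) - log(phi2) + l0))
    denom0 <- phi0 + phi2 * exp(-l0)
    deta[i0] <- -w0 * l0
    dphi0[i0] <- (1 - exp(-l0)) / denom0
    dphi1[i0] <- -exp(-l0) / denom0
  }
  if (any(i1)) {
    l1 <- lam[i1]
    w1 <- if (phi1 == 0) rep(1, sum(i1)) else
      1 / (1 + exp(log(phi1) - log(phi2) - log(l1) + l1))
    denom1 <- phi1 + phi2 * l1 * exp(-l1)
    deta[i1] <- w1 * (1 - l1)
    dphi0[i1] <- -l1 * exp(-l1) / denom1
    dphi1[i1] <- (1 - l1 * exp(-l1)) / denom1
  }
  if (any(i2)) {
    deta[i2] <- y[i2] - lam[i2]
    dphi0[i2] <- -1 / phi2
    dphi1[i2] <- -1 / phi2
  }

  gbeta <- -drop(crossprod(X, deta))
  gphi <- c(sum(dphi0), sum(dphi1))
  grest <- switch(mode,
    both = -drop(phi_jacobian(phi0, phi1) %*% gphi),
    zero = -gphi[1] * phi0 * (1 - phi0),
    one  = -gphi[2] * phi1 * (1 - phi1),
    none = numeric(0)
  )
  c(gbeta, grest)
}

#' Initial values for the ZOIP regression
#'
#' Starting values in the spirit of the fitting recipe the model was
#' designed around: `beta` from a Poisson GLM with log link on the same
#' design, and the inflation masses from the intercept-only ZOIP MLE,
#' itself started at the empirical excess of zeros and ones over the
#' Poisson fit (clipped into the simplex interior).
#'
#' @param y Non-negative integer outcome vector.
#' @param X Design matrix.
#' @return List with `beta`, `phi0`, `phi1`.
#' @export
zoip_init <- function(y, X) {
  beta0 <- tryCatch({
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
    if (!fit$converged) stop("glm.fit did not converge")
    stats::coef(fit)
  }, error = function(e) {
    rlang::inform("Poisson GLM initialization failed; falling back to intercept-only start")
    c(log(max(mean(y), 1e-3)), rep(0, ncol(X) - 1))
  })
  masses <- zoip_init_masses(y)
  list(beta = unname(beta0), phi0 = masses[["phi0"]], phi1 = masses[["phi1"]])
}

# Intercept-only ZOIP MLE for (phi0, phi1), started at empirical excess
# masses max(0, phat_j - Poisson(ybar) pmf at j), clipped interior.
zoip_init_masses <- function(y) {
  ybar <- mean(y)
  p0 <- max(0, mean(y == 0) - stats::dpois(0, ybar))
  p1 <- max(0, mean(y == 1) - stats::dpois(1, ybar))
  p0 <- min(max(p0, 0.01), 0.90)
  p1 <- min(max(p1, 0.005), 0.50)
  if (p0 + p1 > 0.95) {
    s <- 0.95 / (p0 + p1)
    p0 <- p0 * s; p1 <- p1 * s
  }
  fit <- fit_zoip_matrix(
    y, matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)")),
    init = list(beta = log(max(ybar, 1e-3)), phi0 = p0, phi1 = p1),
    compute_vcov = FALSE
  )
  c(phi0 = fit$phi0, phi1 = fit$phi1)
}

#' Fit the ZOIP regression to survey records
#'
#' Data-frame-first interface: builds the design matrix with
#' [build_design_matrix()] and maximizes the ZOIP log-likelihood.
#'
#' @param data Complete-case tibble of survey records (analysis schema).
#' @param inflation Which inflation masses are free: `"both"` (default),
#'   `"zero"`, `"one"`, or `"none"` (plain Poisson regression, used for
#'   oracle checks).
#' @param ... Passed to [fit_zoip_matrix()].
#' @return A `zoip_fit` object; see [fit_zoip_matrix()].
#' @export
#' @examples
#' dat <- generate_pooled_data(zoip_synth_config(n_per_year = c(300, 200, 200, 200), seed = 7))
#' fit <- fit_zoip(dat)
#' glance(fit)
fit_zoip <- function(data, inflation = c("both", "zero", "one", "none"), ...) {
  design <- build_design_matrix(data)
  fit_zoip_matrix(design$y, design$X, inflation = inflation, ...)
}

#' Fit the ZOIP regression to an outcome vector and design matrix
#'
#' Low-level fitting interface. Maximizes the ZOIP log-likelihood by BFGS
#' with an analytic gradient on the unconstrained scale (multinomial-logit
#' transform of the masses), then computes the observed-information
#' variance-covariance matrix.
#'
#' @param y Non-negative integer outcome vector.
#' @param X Design matrix (include the intercept column yourself).
#' @inheritParams fit_zoip
#' @param init Optional list with `beta`, `phi0`, `phi1`; defaults to
#'   [zoip_init()].
#' @param compute_vcov Compute the observed-information vcov (default TRUE).
#' @param control List: `maxit` (default 500), `reltol` (default 1e-12),
#'   `grad_tol` (scaled gradient-norm convergence threshold, default 1e-5).
#' @return Object of class `zoip_fit`: coefficients, `phi0`, `phi1`,
#'   natural-scale `vcov` (rows/cols: coefficients then free masses),
#'   `loglik`, `converged`, `n_iter`, `gradient_norm`, `boundary` flag,
#'   and bookkeeping fields.
#' @export
fit_zoip_matrix <- function(y, X, inflation = c("both", "zero", "one", "none"),
                            init = NULL, compute_vcov = TRUE,
                            control = list()) {
  mode <- match.arg(inflation)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  p <- ncol(X)
  n <- length(y)
  n_free <- p + switch(mode, both = 2L, zero = 1L, one = 1L, none = 0L)
  if (n <= n_free) stop("need more observations than free parameters", call. = FALSE)

  ctrl <- utils::modifyList(list(maxit = 500, reltol = 1e-12, grad_tol = 1e-5),
                            control)
  if (is.null(init)) init <- zoip_init(y, X)
  init$phi0 <- min(max(init$phi0, 1e-4), 0.95)
  init$phi1 <- min(max(init$phi1, 1e-4), 0.95)
  if (init$phi0 + init$phi1 >= 0.99) {
    s <- 0.98 / (init$phi0 + init$phi1)
    init$phi0 <- init$phi0 * s; init$phi1 <- init$phi1 * s
  }
  theta0 <- switch(mode,
    both = c(init$beta, gamma_from_phi(init$phi0, init$phi1)),
    zero = c(init$beta, stats::qlogis(init$phi0)),
    one  = c(init$beta, stats::qlogis(init$phi1)),
    none = init$beta
  )
  ll0 <- -zoip_nll(theta0, y, X, mode)

  opt <- stats::optim(theta0, zoip_nll, zoip_nll_grad, y = y, X = X,
                      mode = mode, method = "BFGS",
                      control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  # one restart tightens the solution when BFGS stops on a flat step
  opt2 <- stats::optim(opt$par, zoip_nll, zoip_nll_grad, y = y, X = X,
                       mode = mode, method = "BFGS",
                       control = list(maxit = ctrl$maxit, reltol = ctrl$reltol))
  if (opt2$value <= opt$value) opt <- utils::modifyList(opt, opt2[c("par", "value", "convergence", "counts")])

  theta_hat <- opt$par
  par <- split_theta(theta_hat, p, mode)
  loglik <- -opt$value
  grad <- zoip_nll_grad(theta_hat, y, X, mode)
  grad_norm <- max(abs(grad)) / max(1, abs(loglik))
  converged <- opt$convergence == 0 && is.finite(grad_norm) &&
    grad_norm < ctrl$grad_tol
  if (loglik < ll0 - 1e-8) converged <- FALSE

  boundary <- (mode %in% c("both", "zero") && par$phi0 < 1e-6) ||
    (mode %in% c("both", "one") && par$phi1 < 1e-6)
  if (boundary) {
    rlang::warn("an inflation mass is within 1e-6 of 0; its standard error is unreliable")
  }

  mass_labels <- switch(mode, both = c("phi0", "phi1"), zero = "phi0",
                        one = "phi1", none = character(0))
  labels <- c(colnames(X), mass_labels)
  vcov_nat <- NULL
  if (compute_vcov) {
    vcov_nat <- zoip_observed_vcov(theta_hat, y, X, mode, labels)
  }

  structure(
    list(
      coefficients = stats::setNames(par$beta, colnames(X)),
      phi0 = par$phi0, phi1 = par$phi1,
      vcov = vcov_nat,
      loglik = loglik,
      converged = converged,
      n_iter = unname(opt$counts["function"]),
      gradient_norm = grad_norm,
      boundary = boundary,
      column_labels = colnames(X),
      mass_labels = mass_labels,
      inflation = mode,
      n = n, p = p,
      init = init
    ),
    class = "zoip_fit"
  )
}

# Observed-information vcov on the natural scale: invert the negative
# Hessian (numDeriv jacobian of the analytic gradient) on the unconstrained
# scale, then apply the delta method through the mass transform.
zoip_observed_vcov <- function(theta_hat, y, X, mode, labels) {
  p <- ncol(X)
  H <- numDeriv::jacobian(function(th) zoip_nll_grad(th, y, X, mode), theta_hat)
  H <- (H + t(H)) / 2 # Hessian of the *negative* log-likelihood
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop(sprintf("observed information is not positive definite (eigenvalue %.3e)",
                 min(ev)), call. = FALSE)
  }
  V_unc <- solve(H)
  par <- split_theta(theta_hat, p, mode)
  J <- diag(length(theta_hat))
  if (mode == "both") {
    J[p + 1:2, p + 1:2] <- phi_jacobian(par$phi0, par$phi1)
  } else if (mode == "zero") {
    J[p + 1, p + 1] <- par$phi0 * (1 - par$phi0)
  } else if (mode == "one") {
    J[p + 1, p + 1] <- par$phi1 * (1 - par$phi1)
  }
  V <- J %*% V_unc %*% t(J)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(labels, labels)
  V
}

#' @export
vcov.zoip_fit <- function(object, ...) object$vcov

#' @export
coef.zoip_fit <- function(object, ...) object$coefficients

#' @export
logLik.zoip_fit <- function(object, ...) {
  structure(object$loglik,
            df = object$p + length(object$mass_labels),
            nobs = object$n, class = "logLik")
}

#' Mean-ratio effect table
#'
#' One row per model parameter: estimate, observed-information SE,
#' mean ratio `exp(estimate)` (blank for the inflation masses, which live
#' on the probability scale), and the two-sided Wald p-value.
#'
#' @param fit A converged `zoip_fit`.
#' @return Tibble with columns `term`, `estimate`, `se`, `mean_ratio`,
#'   `p_value`.
#' @export
mean_ratio_table <- function(fit) {
  stopifnot(inherits(fit, "zoip_fit"))
  if (is.null(fit$vcov)) stop("fit has no vcov; refit with compute_vcov = TRUE", call. = FALSE)
  est <- c(fit$coefficients,
           stats::setNames(c(fit$phi0, fit$phi1)[match(fit$mass_labels, c("phi0", "phi1"))],
                           fit$mass_labels))
  se <- sqrt(diag(fit$vcov))
  is_mass <- names(est) %in% c("phi0", "phi1")
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    mean_ratio = ifelse(is_mass, NA_real_, exp(unname(est))),
    p_value = 2 * stats::pnorm(-abs(unname(est) / unname(se)))
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a ZOIP fit
#'
#' Broom-style coefficient table with the mean ratio and its Wald 95%
#' confidence interval (computed on the log scale and exponentiated).
#'
#' @param x A `zoip_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `mean.ratio`, `conf.low`, `conf.high`.
#' @method tidy zoip_fit
#' @export
tidy.zoip_fit <- function(x, ...) {
  tab <- mean_ratio_table(x)
  z <- tab$estimate / tab$se
  tibble::tibble(
    term = tab$term,
    estimate = tab$estimate,
    std.error = tab$se,
    statistic = z,
    p.value = tab$p_value,
    mean.ratio = tab$mean_ratio,
    conf.low = ifelse(is.na(tab$mean_ratio), tab$estimate - 1.96 * tab$se,
                      exp(tab$estimate - 1.96 * tab$se)),
    conf.high = ifelse(is.na(tab$mean_ratio), tab$estimate + 1.96 * tab$se,
                       exp(tab$estimate + 1.96 * tab$se))
  )
}

#' Glance at a ZOIP fit
#'
#' @param x A `zoip_fit`.
#' @param ... Unused.
#' @return One-row tibble: log-likelihood, AIC, BIC, inflation masses,
#'   sample size, parameter counts, convergence metadata.
#' @method glance zoip_fit
#' @export
glance.zoip_fit <- function(x, ...) {
  k <- x$p + length(x$mass_labels)
  tibble::tibble(
    logLik = x$loglik,
    AIC = -2 * x$loglik + 2 * k,
    BIC = -2 * x$loglik + log(x$n) * k,
    phi0 = x$phi0,
    phi1 = x$phi1,
    nobs = x$n,
    n_coef = x$p,
    converged = x$converged,
    n_iter = x$n_iter,
    gradient_norm = x$gradient_norm
  )
}

#' @export
print.zoip_fit <- function(x, ...) {
  cat("Zero-and-one-inflated Poisson regression fit\n")
  cat(sprintf("  n = %d, coefficients = %d, inflation mode = %s\n",
              x$n, x$p, x$inflation))
  cat(sprintf("  log-likelihood = %.3f, converged = %s\n",
              x$loglik, x$converged))
  cat(sprintf("  phi0 = %.4f, phi1 = %.4f\n", x$phi0, x$phi1))
  invisible(x)
}

#' Forest plot of mean ratios
#'
#' Dot-and-interval plot of `exp(beta_j)` with Wald 95% intervals for every
#' regression coefficient except the intercept.
#'
#' @param object A `zoip_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot zoip_fit
#' @export
autoplot.zoip_fit <- function(object, ...) {
  td <- tidy(object)
  td <- td[!(td$term %in% c("(Intercept)", "phi0", "phi1")), ]
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mean.ratio,
                                   y = stats::reorder(.data$term, .data$mean.ratio))) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "mean ratio (log scale)", y = NULL,
                  title = "ZOIP regression mean ratios with Wald 95% CI") +
    ggplot2::theme_minimal()
}
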