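# Shared fixtures: small in-code datasets and a hand-built fit object for
# contrast arithmetic on known coefficients.

# A tiny valid analysis-schema tibble (all-reference profile unless edited).
make_records <- function(n = 10, survey_year = "2011") {
  lev <- sanc_levels()
  tibble::as_tibble(c(
    list(sanc_visits = rep(2L, n), survey_year = rep(survey_year, n)),
    lapply(lev, function(l) rep(l[1], n))
  ))
}

# A zoip_fit-shaped object from fixed coefficients, for delta-method and
# mean-ratio arithmetic against hand-computed values.
make_fit <- function(beta, se = NULL, phi0 = 0.172, phi1 = 0.011) {
  labels <- names(beta)
  all_labels <- c(labels, "phi0", "phi1")
  if (is.null(se)) se <- rep(0.01, length(all_labels))
  V <- diag(se^2)
  dimnames(V) <- list(all_labels, all_labels)
  structure(
    list(coefficients = beta, phi0 = phi0, phi1 = phi1, vcov = V,
         loglik = NA_real_, converged = TRUE, n_iter = 0L,
         gradient_norm = 0, boundary = FALSE,
         column_labels = labels, mass_labels = c("phi0", "phi1"),
         inflation = "both", n = 0L, p = length(labels), init = NULL),
    class = "zoip_fit"
  )
}

# Small synthetic pooled dataset for pipeline-level tests.
small_config <- function(seed = 42, n_per_year = c(800, 500, 500, 500), ...) {
  suppressMessages(zoip_synth_config(n_per_year = n_per_year, seed = seed, ...))
}

small_data <- function(seed = 42, ...) {
  generate_pooled_data(small_config(seed = seed, ...))
}
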