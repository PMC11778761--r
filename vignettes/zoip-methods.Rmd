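---
title: "Modelling skilled antenatal care visit counts with zero-and-one inflation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling skilled antenatal care visit counts with zero-and-one inflation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoipanc)
```

## The problem

Counts of skilled antenatal care (SANC) visits in household surveys from
low- and middle-income countries show two departures from a Poisson law at
once: an excess of zeros (mothers who never reach a skilled provider) and a
smaller excess of ones (mothers who attend exactly once, often only to
confirm the pregnancy). A Poisson or negative-binomial regression absorbs
neither cleanly, and a zero-inflated model absorbs only the first. zoipanc
implements the zero-and-one-inflated Poisson (ZOIP) analysis pipeline for
pooled multi-wave survey data: descriptive tables, nonparametric screening,
a score test that asks whether the two inflations are jointly present, the
ZOIP regression itself, and delta-method trend contrasts for a
residence-by-survey-year interaction.

## The model

A ZOIP outcome is a three-component mixture: a point mass at 0 with weight
$\varphi_0$, a point mass at 1 with weight $\varphi_1$, and a
Poisson($\lambda$) component with weight
$\varphi_2 = 1 - \varphi_0 - \varphi_1$:

$$
P(Y = y) =
\begin{cases}
\varphi_0 + \varphi_2 e^{-\lambda} & y = 0\\
\varphi_1 + \varphi_2 \lambda e^{-\lambda} & y = 1\\
\varphi_2\, \lambda^{y} e^{-\lambda} / y! & y > 1.
\end{cases}
$$

Covariates enter the Poisson mean through a log link,
$\log \lambda_i = x_i^\top \beta$; the masses $\varphi_0, \varphi_1$ are
constant (no covariates), because interest centres on the mean of the count
component. A coefficient is read as a *mean ratio* $e^{\beta_j}$: the
multiplicative change in $\lambda$ per unit change of $x_j$, holding the
rest fixed. The log-likelihood splits into the contributions of the zeros,
the ones, and the larger counts; both one-observation terms are sums of two
exponentials and are evaluated by log-sum-exp so large $\lambda$ cannot
underflow (`dzoip()` is exact in log space for counts into the hundreds;
factorials go through `lgamma`).

The design matrix is fixed: an intercept, 19 treatment-coded dummies over
12 covariates (reference levels: urban, age <20, no education for either
parent, poor, first birth, non-working, non-exposed, no decision
participation, violence non-justified, unwanted pregnancy, no terminated
pregnancy), the survey year coded 1–4 (2011, 2014, 2017-18, 2022) as a
quantitative trend, and the rural-by-year interaction — 22 columns in all.

## Estimation

`fit_zoip()` maximizes the likelihood by BFGS with an analytic gradient.
Two choices matter:

* **Unconstrained masses.** $(\varphi_0, \varphi_1)$ are optimized through
  a multinomial-logit transform, so any optimizer step yields a valid
  point strictly inside the probability simplex. A side effect is that a
  boundary maximum ($\varphi = 0$) is approached asymptotically; estimates
  within $10^{-6}$ of zero are flagged and their Wald standard errors
  marked unreliable.
* **Initial values.** $\beta$ starts at the Poisson GLM solution on the
  same design; the masses start at the intercept-only ZOIP MLE, itself
  started at the empirical excess of zeros and ones over a moment-matched
  Poisson fit. In practice the surface is well behaved: five dispersed
  random starts reach the same maximum to within $10^{-4}$ log-likelihood
  units on the standard test fixture.

Convergence requires both an optimizer success code and a scaled gradient
norm below $10^{-5}$ (relative tolerance $10^{-12}$, at most 500
iterations, plus one restart to tighten flat steps). Standard errors come
from the observed information: the Hessian of the log-likelihood at the
MLE on the unconstrained scale (numerical differentiation of the analytic
gradient), inverted and mapped to the natural scale by the transform
Jacobian. P-values are two-sided Wald normal. With both masses fixed at
zero the model *is* a Poisson GLM, and the test-suite requires agreement
with `stats::glm` to $10^{-6}$ — a structural oracle rather than a
statistical one.

## The score test

Before fitting, `score_test_zero_one()` asks whether inflation is present
at all. Under the Poisson null with $\hat\lambda = \bar y$, the score of
the two mass parameters is

$$
U = \Big(\textstyle\sum_i \big[\tfrac{1\{y_i=0\}}{p_0(\hat\lambda)} - 1\big],\;
\sum_i \big[\tfrac{1\{y_i=1\}}{p_1(\hat\lambda)} - 1\big]\Big),
$$

with $p_j$ the Poisson pmf at $j$. Because $\lambda$ is estimated, the
covariance of $U$ is the efficient (partial) information — the Schur
complement removing the $\lambda$ direction — giving per observation
$V_{11} = (1-p_0)/p_0 - \lambda$, $V_{12} = -\lambda$,
$V_{22} = (1-p_1)/p_1 - (1-\lambda)^2/\lambda$. The statistic
$U^\top (nV)^{-1} U$ is referred to $\chi^2_2$ (three parameters, one
estimated under the null). The cited construction is not printed in full
anywhere we could copy it from, so the package *proves* its calibration
instead of assuming it: the test-suite checks the null rejection rate,
the uniformity of null p-values, and agreement with a parametric
bootstrap that re-simulates Poisson samples at $\hat\lambda$. The
quadratic form is two-sided; a boundary-corrected mixture-of-chi-square
reference would be more powerful one-sided but is deliberately not
implemented, matching the $\chi^2$ reference the analysis protocol states.

## Trend contrasts

With the year coded 1–4 and a rural indicator $r$, the fitted log mean
contains $\beta_r r + \beta_t t + \beta_{rt} r t$. Two derived tables
summarize the interaction: the rural-vs-urban mean ratio in survey year
$t$, $\exp(\beta_r + t\,\beta_{rt})$, and the per-coded-year trend ratio
within each area, $\exp(\beta_t)$ (urban) and $\exp(\beta_t + \beta_{rt})$
(rural). `contrast_mean_ratio()` computes any such contrast $a$ with the
delta method: $\mathrm{SE}(e^{a^\top\hat\beta}) =
e^{a^\top\hat\beta}\sqrt{a^\top \hat V a}$. The default 95% interval is
computed on the log scale and exponentiated, which keeps the bounds
positive and matches the parametric-bootstrap interval to within 5% on
the endpoints in the tests; a symmetric-on-ratio interval is available
behind `ci_scale = "ratio"` for sensitivity.

## The synthetic generator

Real pooled survey microdata of this kind are restricted-access, so the
package carries its own ground truth. `zoip_synth_config()` defaults to
the published study conditions: 6956/4304/4819/4712 records across the
four waves (pooled n = 20791), per-year covariate marginals from the
published percent-distribution table, outcome coefficients from the
published regression, and masses $\varphi_0 = 0.172$,
$\varphi_1 = 0.011$. Covariates are drawn independently within year —
only marginals are published, so independence is a stated simplification;
real survey covariates are correlated (education with wealth, residence
with media exposure), which means passing recovery tests here demonstrate
correctness of the estimator, not robustness to confounded designs. One
published marginal (terminated pregnancy, 2022) sums past 100% and is
renormalized with a message. One master seed drives deterministic
per-stage child seeds, so covariates, outcomes and missingness are
individually reproducible. Missingness, when requested, is injected
completely at random per field, matching the complete-case analysis the
pipeline applies.

## Problem sizes and numerical tolerances in the test-suite

The suite runs on one CPU in about a minute, with simulation sizes chosen
to keep Monte-Carlo error well inside each asserted band:

* Score-test size: 1000 null replicates at n = 2000, $\lambda = 2$
  (binomial SE of the rejection rate ≈ 0.007 against an accepted band of
  0.03–0.07); power: 200 replicates at $(\varphi_0, \varphi_1) =
  (0.3, 0.1)$.
* SE calibration and Wald coverage: 150 replicates of a reduced
  4-coefficient model at n = 2000 — the calibration being checked is a
  property of the estimator, not of the design width.
* End-to-end recovery: 25 replicates at n = 5000 plus one full-size
  (n = 20791) fit. At n = 5000 the true $\varphi_1 = 0.011$ lies within
  about two standard errors of the simplex boundary, so individual fits
  can legitimately collapse it to zero; the scaled-down check is
  therefore ensemble unbiasedness of $\hat\varphi_1$, while the absolute
  recovery bands (±0.010 for $\varphi_0$, ±0.005 for $\varphi_1$) are
  asserted at full size, where they correspond to roughly 2–4 reported
  standard errors.

Rank-test p-values use the tie-corrected chi-square/normal
approximations (counts are heavily tied); an exact enumeration mode
exists for two groups of at most ten. At twelve observations the
chi-square approximation to Kruskal-Wallis is accurate near the
rejection threshold (within 0.005 of the exact permutation p at
p ≈ 0.05) but coarsens toward p = 1, where the permutation distribution
is discrete — agreement is asserted where the test operates.

## Known limitations

* No covariates on the inflation masses, no negative-binomial count
  component, no EM variant — direct maximization of the stated
  likelihood only.
* No survey design features (weights, strata, clusters); the regression
  treats records as independent.
* Wald inference for $\varphi_1$ is asymmetric near the boundary; at
  moderate n its nominal intervals undercover (the test-suite documents
  this rather than hiding it).
* The score test is intercept-only, as applied in the pipeline; a
  covariate-adjusted variant is out of scope.
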