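# zoipanc

Zero-and-one-inflated Poisson (ZOIP) modelling of skilled antenatal care
(SANC) visit counts from pooled household surveys.

Counts of SANC visits typically pile up at zero (no skilled care at all)
and, to a lesser degree, at one (a single confirmation visit), beyond what
any Poisson mean can absorb. zoipanc is for epidemiologists and
biostatisticians analysing such data: it implements the ZOIP mixture

    P(Y=0) = phi0 + phi2 * exp(-lambda)
    P(Y=1) = phi1 + phi2 * lambda * exp(-lambda)
    P(Y=y) = phi2 * lambda^y * exp(-lambda) / y!,   y > 1,
    phi2 = 1 - phi0 - phi1,   log(lambda_i) = x_i' beta,

with maximum-likelihood estimation (BFGS on an unconstrained
parameterization, analytic gradient, observed-information standard
errors), and the full analysis pipeline around it:

* schema validation and survey-recode rules (wealth, media exposure,
  decision participation, violence opinion, pregnancy intention),
  complete-case filtering, and a fixed 22-column design matrix with the
  survey year coded 1–4 and a rural-by-year interaction;
* descriptive tables (mean ± SD with 95% CI, percent distributions,
  group means), Kruskal-Wallis screening and pairwise Mann-Whitney
  follow-up with tie correction;
* a partial score test for *simultaneous* zero and one inflation under a
  Poisson null (chi-square with 2 df), validated against a parametric
  bootstrap;
* coefficients reported as mean ratios `exp(beta_j)`, and delta-method
  confidence intervals for interaction contrasts such as the
  rural-vs-urban mean ratio in a given survey year,
  `exp(beta_rural + t * beta_interaction)`;
* a synthetic pooled-survey generator with known ground truth (published
  per-year marginals, coefficients, and inflation masses 0.172 / 0.011),
  so every stage is testable without restricted survey microdata.

All user-facing functions take a data frame first and return tibbles;
fitted models support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Generate a full-size synthetic pooled dataset at the default study
conditions (n = 20791 across four survey waves) and run the whole
pipeline:

```r
library(zoipanc)

cfg <- zoip_synth_config(seed = 1)
dat <- generate_pooled_data(cfg)
rep <- run_full_analysis(data = dat, quiet = TRUE)
rep
#> SANC-visits analysis report
#>   records: 20791 complete of 20791 input
#>   score test: statistic 8440.11 (df 2), p 0
#>   ZOIP fit: loglik -39678.51, phi0 0.1745, phi1 0.0118
```

The score test overwhelmingly rejects the plain-Poisson null, and the fit
recovers the generating inflation masses (0.172 and 0.011) within one
standard error. The headline coefficients:

```r
dplyr::filter(tidy(rep$fit),
              term %in% c("residence_rural", "year_code", "rural_x_year"))
#>   term            estimate std.error statistic  p.value mean.ratio
#> 1 residence_rural  -0.499    0.0237     -21.1   1.3e-98      0.607
#> 2 year_code         0.0393   0.00678      5.80  6.5e- 9      1.04
#> 3 rural_x_year      0.104    0.00840     12.3   5.2e-35      1.11
```

Rural mothers average about 40% fewer visits than urban mothers at the
first wave (mean ratio 0.61), visits grow about 4% per coded survey year
in urban areas, and the positive interaction means the rural-urban gap
narrows over time:

```r
rep$trend
#> Rural-vs-urban mean ratio by survey year:
#>  survey_year ratio ci_low ci_high
#>         2011 0.673  0.652   0.695
#>         2014 0.747  0.731   0.763
#>      2017-18 0.828  0.812   0.846
#>         2022 0.919  0.892   0.947
#> Per-unit-year trend ratio by area:
#>  residence ratio ci_low ci_high
#>      urban  1.04   1.03    1.05
#>      rural  1.15   1.14    1.17
```

`write_tables(rep, "out/")` emits the four report tables, the two
figure-data CSVs and a JSON report. A thin command-line front end with
`simulate` and `report` subcommands ships in `inst/scripts/zoipanc`.

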