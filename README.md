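# claimsbias

Quantifying external-validity bias in commercial healthcare-claims data.

## The problem

Commercial insurance claims databases are among the largest patient-level
datasets in existence, but they are a *nonrandom* sample: inclusion
requires commercial coverage, and commercial coverage is patterned by
neighborhood socioeconomic conditions. Whenever an outcome is associated
with those same social determinants of health (SDOH), rates estimated from
a claims cohort are biased with respect to the general population.
`claimsbias` is for biostatisticians and health-services researchers who
want to quantify that bias against a ground-truth capture of the outcome
(for inpatient procedures: all-payer state discharge data with census
denominators), explain it with SDOH, and study how it changes as the
target population is restricted toward the claims sampling frame.

## The method

For each procedure *k*:

- **rates** — claims: `Y_C / T_C` with `T_C` the summed person-years of
  coverage; reference: `Y_R / N` with `N` the census population (constant
  over the year). 95% intervals are exact Garwood (chi-square) Poisson
  limits.
- **relative bias** — `B = (Y_C/T_C) / (Y_R/N)`, with a delta-method
  interval on the log ratio: `exp(log B ± 1.96 √(1/Y_C + 1/Y_R))`.
  `B = 1` means the claims cohort reproduces the target-population rate.
- **SDOH association** — zip-level Poisson regression with population
  offset, `log(E[Y_i]/pop_i) = β₀ + β₁·SDOH_i`; `β₁` measures how strongly
  the procedure concentrates in deprived areas.
- **meta-regression** — OLS of `log B` on `β₁` across procedures; slope,
  R² and p-value summarize how much of the bias SDOH explains. Under
  log-linear selection `e^{d·s}` with `s ~ N(0, σ²)`, the slope has the
  analytic value `d·σ²`, which the package's exact oracle and synthetic
  generator reproduce.

Because real claims and all-payer discharge extracts are proprietary, the
package includes a seeded synthetic-data generator (SDOH-dependent
insurance composition, claims selection, partial-year coverage) plus an
exact analytic oracle (`expected_relative_bias()`) so the whole pipeline is
verifiable end to end.

## Worked example

The published-style overall worked example — 114,756 claims discharges over
2,756,043 enrollees averaging 303.6 coverage days, against 2,945,667
reference discharges over a census population of 42,062,788:

```r
library(claimsbias)
claims    <- estimate_rate(114756, 2756043 * 303.6 / 365)  # 5.01 / 100 PY
reference <- estimate_rate(2945667, 42062788)              # 7.003 / 100 PY
relative_bias(claims, reference)
#> # A tibble: 1 × 7
#>   procedure_id ratio ci_low ci_high claims_count reference_count zero_claims
#>   <chr>        <dbl>  <dbl>   <dbl>        <dbl>           <dbl> <lgl>
#> 1 overall      0.715  0.711   0.719       114756         2945667 FALSE
```

The claims cohort underestimates the overall discharge rate by ~28%
(ratio 0.715, CI 0.711–0.719).

A full synthetic study, with selection avoiding deprived areas
(`d = -0.5`, SDOH sd 1), analyzed against two target populations:

```r
res <- run_pipeline(study_config(
  seed = 7, n_zips = 300, n_procedures = 40,
  mean_zip_population = 5000,
  beta0_range = log(c(5e-4, 3e-3)),
  selection = selection_model(intercept = -3.5, sdoh_coefficient = -0.5),
  targets = c("all", "commercial")
))
res$comparison
#> # A tibble: 2 × 11
#>   target      slope intercept r_squared  p_value n_procedures n_excluded
#> 1 all        -0.510   -0.0800     0.701 1.65e-11           40          0
#> 2 commercial -0.283   -0.0656     0.422 5.68e- 6           40          0
#>   beyond_1.5 beyond_2 iqr_q1 iqr_q3
#> 1      0.225    0.05   0.755   1.24
#> 2      0.1      0.025  0.818   1.10
attr(res$comparison, "attenuation")
#> [1] 0.5550398
```

The all-population meta-slope (−0.51) shows that procedures concentrated in
deprived zips are systematically underestimated; restricting the target to
the commercially insured roughly halves the association (attenuation 0.56),
exactly the behavior the method is built to expose. `autoplot(res$fits$all)`
draws the meta-regression scatter and `plot_forest(res$bias$all)` the
per-procedure forest plot.

See `vignettes/external-validity-bias.Rmd` for the model, the generator's
assumptions, and every numerical convention.

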