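# floodepi

Estimating how large-scale flood exposure changes cause-specific
hospitalisation rates in an elderly population, using a self-matched
design and conditional quasi-Poisson distributed-lag models.

## The problem and the design

Severe floods plausibly affect health well beyond drownings and acute
injuries — through interrupted care, mould and dampness, stress, and
displacement — and the effects may build up over weeks. Admission-level
claims data aggregated to ZIP-code days can measure this, but
hospitalisation rates differ enormously between ZIP codes and across the
calendar. `floodepi` implements the standard epidemiological answer: a
**self-matched (case-crossover-style) design**. Every *exposure period*
(a maximal run of consecutive days on which a ZIP code is flood-exposed)
is matched to **two non-flooded control windows in the same ZIP code and
the same days of the year, in other years**. Comparing each ZIP with
itself at the same time of year removes time-invariant ZIP confounding
and seasonality by construction.

A ZIP-day counts as exposed when a mapped flood covers **at least 0.5 %
of the ZIP's surface area or at least 5 square miles** (both thresholds
configurable), and only floods caused by heavy rain or tropical storms
are analysed by default. Outcomes are counted over the exposure window
(lag 0) and each of the following lag weeks (4 by default, 12 for the
extended secondary analysis), for both the exposed and the control arms.

## The model

For stratum *s* (one exposure period plus its two controls), arm/lag
window *i* with outcome count `y_i`, person-days `T_i` and design row
`x_i`, the model is Poisson-family with stratum fixed effects:

    log E[y_i] = alpha_s + x_i' beta + log T_i

`x_i` contains one indicator per exposure lag (1 iff the window is the
exposed arm at that lag) plus natural splines with 2 df for calendar
year and for the window means of temperature, humidity, wind speed,
PM2.5, NO2 and O3. The fit **profiles the stratum intercepts in closed
form** inside each Newton step — numerically identical to conditional
Poisson estimation — and scales the covariance by the Pearson
quasi-likelihood dispersion `phi = X²_P / (n − p − S)`. Effects are
reported as **relative percentage changes** `(RR − 1) × 100` with
`RR = exp(beta_l)`, and confidence intervals use Bonferroni-corrected
normal quantiles `1 − alpha/(2m)`.

Because the motivating claims data are restricted, the package ships a
**synthetic-data generator** (`sim_config()`, `simulate_flood_study()`)
that emulates all five inputs — ZIP-day flood tables, hospitalisation
counts, daily covariates, ZIP-year denominators, and census covariates —
with seasonality, secular trend, covariate confounding, gamma-frailty
overdispersion and *known injected lag effects*, so the whole pipeline
is testable against ground truth.

## Worked example

```r
library(floodepi)

cfg <- sim_config(
  n_zips = 12, date_start = as.Date("2000-01-01"),
  date_end = as.Date("2007-12-31"), n_events = 12,
  causes = c(respiratory = 10.5, circulatory = 23),
  lag_effects = list(respiratory = c(log(1.30), log(1.20), log(1.10), 0, 0)),
  seed = 2026)

res <- run_flood_pipeline(cfg, causes = "respiratory")
res$strata
#> matched_strata: 41 of 41 exposure periods matched (2 controls each)
res$fits$respiratory
#> Conditional quasi-Poisson fit (cause: respiratory)
#>    615 rows, 41 strata, 19 coefficients; converged in 5 iterations
#>   dispersion: 3.073  deviance: 1773.74
#>   lag terms (log RR +/- SE):
#>     exp_lag0     0.1748  (0.1262)
#>     exp_lag1     0.0868  (0.1083)
#>     exp_lag2    -0.1365  (0.1207)
#>     exp_lag3     0.0442  (0.1116)
#>     exp_lag4    -0.0439  (0.1156)
res$effects[, c("cause", "lag_label", "pct_change", "ci_low", "ci_high")]
#>         cause lag_label pct_change ci_low ci_high
#> 1 respiratory         0      19.10  -14.0    64.9
#> 2 respiratory         1       9.06  -17.5    44.2
#> 3 respiratory         2     -12.76  -36.1    19.1
#> 4 respiratory         3       4.52  -21.6    39.3
#> 5 respiratory         4      -4.30  -28.9    28.9
#> 6 respiratory      mean       2.54  -13.4    21.4
```

Twelve flood events produced 41 exposed ZIP-periods, all matched to two
flood-free control windows. The lag-0 estimate (+19.1 %) is the change
in respiratory admissions during flood exposure relative to matched
control windows; at this deliberately small demonstration scale the
Bonferroni-corrected CIs are wide but cover the injected truth (+30 % at
lag 0, decaying over two weeks). Stratified analyses work the same way
via `run_stratified()` (severity, season, admission type, or median
splits of ZIP-level census covariates).

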