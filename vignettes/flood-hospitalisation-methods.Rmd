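---
title: "Methods: self-matched distributed-lag analysis of flood exposure and hospitalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: self-matched distributed-lag analysis of flood exposure and hospitalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical model, the design decisions that
were genuinely open, the synthetic-data generator, and the numerical
choices in `floodepi`. It is the package's reference for *why* things
are the way they are; the README shows *how* to use them.

## 1. Design: exposure periods and self-matched controls

**Exposure.** A ZIP-day is flood-exposed when the mapped flooded
fraction of the ZIP's surface is at least 0.5 % *or* the flooded area is
at least 5 square miles (`classify_exposure()`; both comparisons
inclusive, both thresholds configurable for sensitivity analyses).
Maximal runs of consecutive exposed days form *exposure periods*
(`build_exposure_periods()`); a single unexposed day splits a period. A
period inherits the maximum severity of its days (moderate < high <
extreme) and the union of flood-cause labels; by default only periods
involving heavy rain or tropical storms are analysed. The exposure rule
is applied per day of the event footprint. When flood information
arrives as a raster, `zonal_flood_fraction()` aggregates a binary flood
grid over a congruent zone-id grid; ZIP geography is otherwise
abstracted into the tabular input.

**Matching.** Each period is matched to **two** flood-free control
windows in the same ZIP, at the same month-day span, in other study
years (`build_strata()`). Decisions the design left open, and the
defaults chosen:

- *Which two of the eligible years?* `nearest_balanced`: the nearest
  eligible year before and the nearest after the exposure year
  (mirroring "years preceding or following"); if one side is empty, the
  two nearest on the other side. A seeded `random_2` policy exists for
  sensitivity analysis.
- *Must the control's lag weeks also be flood-free?* Yes by default: a
  flood inside a control's lag tail would contaminate the control lag
  rates. `check_tail = FALSE` relaxes this.
- *Leap days.* Control windows anchor the exposed period's **start**
  month-day (Feb 29 maps to Feb 28 in non-leap years) and preserve the
  duration in calendar days, so a flood on Feb 29 is controlled on
  Feb 28 and every stratum's three arms have equal length. For periods
  *spanning* Feb 29 the control end month-day may drift by one day;
  person-time offsets absorb any residual asymmetry.
- *Later floods inside an exposed period's own lag weeks* are kept
  (intention-to-treat-style); strata with fewer than two eligible
  controls are dropped and recorded in the attrition log.

## 2. Model and estimation

With stratum $s$, window $i$, count $y_i$, person-days $T_i$:

$$\log E[y_i] = \alpha_s + \sum_{l=0}^{L} \beta_l\,
  \mathbb{1}\{\text{arm}_i = \text{exposed},\ \text{lag}_i = l\}
  + f(\text{year}_i) + \sum_v g_v(\bar z_{vi}) + \log T_i$$

where $f$ and each $g_v$ are natural cubic splines with 2 df (boundary
knots at the data range, interior knot at the median — the default knot
placement of `splines::ns`, on which `natural_spline_basis()` is built),
evaluated on the decimal year at the window midpoint and on window means
of tmax, rhmax, wind, PM2.5, NO2 and O3. Matching already absorbs ZIP
effects and season; the splines mop up long-term trends and short-term
meteorology. Spline bases are fit once per cause on the full analytical
dataset, matching the single model fit. Lag-0 windows of unequal length
are handled through the offset, not by standardising to weekly rates,
preserving the count likelihood. Person-time uses ZIP-year enrolment
(the denominators' native cadence); day-wise interpolation would be
spurious precision.

**Profiled IRLS.** Given $\beta$, each $\alpha_s$ has the closed-form
maximiser $\hat\alpha_s(\beta) = \log \sum_s y_i - \log \sum_s
e^{x_i'\beta + \log T_i}$. `fit_conditional_quasipoisson()` alternates
this profiling with a Newton step on $\beta$ computed from the
within-stratum weight-centred design, i.e. on the profile score
$X'(y-\mu)$ and profile information $\tilde X' W \tilde X$ (the Schur
complement of the full information with respect to the intercepts). For
Poisson data this reproduces the conditional-likelihood point estimates
exactly; the test suite asserts equality (to 1e-6) with an independent
dummy-variable Poisson maximum-likelihood fit on random fixtures, and
equality of coefficients, dispersion and standard errors with
`glm(..., family = quasipoisson())` on an explicit-dummy design.

**Quasi-Poisson dispersion.** $\hat\phi = \chi^2_{\text{Pearson}} /
(n - p - S)$ with $S$ the retained strata — the residual degrees of
freedom subtract the profiled intercepts. The covariance is $\hat\phi$
times the inverse profile information. No dispersion floor is applied
by default (`dispersion_floor = 1` is available).

**Effects.** `lag_effects()` reports $(e^{\beta_l} - 1) \times 100$ with
CIs from normal quantiles $1 - \alpha/(2m)$; $m$ is a visible, logged
argument defaulting to the number of lag estimates in the model
($L + 1$), since the multiplicity family is an analysis-level choice.
`mean_effect()` averages the lag coefficients with uniform weights on
the log scale (variance $c'Vc$); an arithmetic mean of per-lag
percentage changes is available via `scale = "pct"` because "mean
percentage change" is ambiguous between the two.

**Degenerate inputs.** Strata with zero total count are dropped (their
conditional likelihood is constant) with a warning; rank-deficient
designs raise an error naming the collinear columns; non-convergence
after 100 iterations returns a flagged fit. Convergence is max
$|\Delta\beta| < 10^{-10}$ from a $\beta = 0$ start.

## 3. Stratified and secondary analyses

`run_stratified()` re-fits per stratum level. Severity is dichotomised
moderate vs {high, extreme} exactly as reported. The warm season is
April–September by the exposed period's start date (the cold/warm
boundary is not standardised anywhere; it is configurable). Admission
type is a row-level filter: counts are re-aggregated under the filter
and the model re-fit on all strata. ZIP-level splits (% Black
residents, median income, poverty rate) use a median split over the
exposed ZIPs — the analysis population — labelling strictly-above-median
ZIPs "higher"; an explicit threshold can be supplied. Stratum-level and
ZIP-level splits partition whole matched strata, never dividing one.
Subcause analyses reuse the pipeline with a user-supplied code-to-cause
mapping (`map_diagnosis_codes()`) and the inclusion rule that a subcause
needs at least 20 000 admissions in the sample (`filter_subcauses()`).
The extended secondary analysis sets `n_lags = 12`.

## 4. The synthetic world

The generator emulates the five study inputs at their native
resolutions: ZIP-day flood exposure, ZIP-day-cause admission counts
split by admission type, daily ZIP covariates, ZIP-year enrolment, and
once-per-ZIP census covariates.

- **Study conditions.** Defaults mirror the motivating study: a 17-year
  window (2000–2016), 72 flood events with severity mix
  (0.56, 0.14, 0.30) and flood-cause mix (0.81, 0.19), durations from a
  discretised lognormal truncated to 1–42 days, 13 cause categories
  whose baseline rates imply a leading-cause ordering (circulatory,
  respiratory, digestive, injury) and an overall admission rate
  plausible for an elderly fee-for-service population, and 4 lag weeks.
- **Counts.** $y \sim \text{Poisson}(g\mu)$ with $\log\mu$ containing
  the population offset, baseline log rate, a seasonal sinusoid
  (amplitude 0.1 on the log scale), a secular trend (0.01/year),
  per-SD covariate effects (covariates are standardised internally so
  configured effects are scale-free), and the injected
  $\text{lag\_effects}[c][l]$ wherever the day falls in lag window $l$
  of an exposure — exposure being classified by the same rule the
  pipeline uses. $g$ is a gamma frailty with mean 1 and variance
  `dispersion − 1`, shared within (ZIP, week): quasi-Poisson only
  models variance inflation, and shared frailties add realistic
  within-window correlation. Because the frailty acts multiplicatively,
  the realised Pearson dispersion grows with the mean window count
  ($\phi \approx 1 + v\,\bar\mu$), so the configured value is a
  variance-component target, not the realised $\hat\phi$; tests
  therefore check $\hat\phi \approx 1$ at `dispersion = 1` and strict
  monotonicity in the frailty variance, not equality.
- **Covariates.** Seasonal sinusoids plus AR(1) noise (lag-1
  correlation 0.7), ZIP-specific levels; census covariates drawn once
  per ZIP.
- **Identifiability of the truth.** Flood events never overlap within a
  ZIP and are separated by at least the full lag tail, so every day has
  at most one true lag assignment; overlap handling in the analysis
  code is exercised separately with hand-built fixtures.

What the generator deliberately does *not* emulate: real claim-record
layouts, spatial correlation of floods with covariates, ZIP boundary
changes, enrolment migration after disasters, and reporting artefacts.
Passing recovery tests therefore demonstrates the *estimator* is
correct under the stated data-generating process, not that real claims
analyses are unbiased.

## 5. Validation study sizes

The package's calibration checks run at two scales, chosen once as part
of the validation design. A full-scale run (50 ZIPs, 17 years, 30
events, overdispersed and confounded defaults) checks that every lag
coefficient lands within 3 estimated SEs of an injected decaying
profile (RR 1.5, 1.3, 1.2, 1.1, 1.0 by lag). Calibration replicates
(200 for coverage, 200 for type-I error) use 10 ZIPs over 6 years with
10 events and a single all-cause outcome, with `dispersion = 1` and
zero covariate effect sizes: CI coverage and size are properties of the
estimator under correct specification, so the replicate generator is
run exactly on the model's assumptions; confounded recovery is covered
by the full-scale run. Uncorrected 95 % CI coverage per lag, the
fraction of null CIs excluding zero, and the Bonferroni ($m = 5$)
family-wise error are computed by `tests/testthat/test-acceptance.R`
and recomputed from scratch by `scripts/acceptance.R`.

## 6. Known limitations

- The conditional quasi-Poisson variance treats windows within a
  stratum as independent given the frailty-free mean; strongly
  autocorrelated shocks within a stratum are only captured through the
  global dispersion.
- Matching is calendar/ZIP only (by design); no covariate-based
  matching.
- The geospatial path operates on congruent grids supplied as matrices;
  reading georeferenced rasters and reconciling ZIP vs ZCTA polygons is
  out of scope.
- Effect-modification is addressed by stratification, not interaction
  models, matching the motivating design.
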