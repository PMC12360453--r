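# Synthetic world generator: validation, determinism, calendar coverage,
# event properties, and the count model's moments.

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(n_zips = 0), "n_zips")
  expect_error(sim_config(date_start = as.Date("2005-01-01"),
                          date_end = as.Date("2004-01-01")), "date_end")
  expect_error(sim_config(causes = c(a = -1)), "causes")
  expect_error(sim_config(dispersion = 0.5), "dispersion")
  expect_error(sim_config(lag_effects = list(circulatory = c(0, 0))),
               "lag_effects")
  expect_error(sim_config(lag_effects = list(nosuch = rep(0, 5))),
               "lag_effects")
  expect_error(sim_config(population_range = c(100, 10)),
               "population_range")
})

test_that("the same seed reproduces the world and counts field-for-field", {
  cfg <- sim_config(n_zips = 4, date_end = as.Date("2002-12-31"),
                    n_events = 4, causes = c(all = 40), seed = 11)
  s1 <- simulate_flood_study(cfg)
  s2 <- simulate_flood_study(cfg)
  expect_identical(s1$world$covariates, s2$world$covariates)
  expect_identical(s1$world$population, s2$world$population)
  expect_identical(s1$exposures, s2$exposures)
  expect_identical(s1$counts, s2$counts)
})

test_that("every ZIP-day in the window has one covariate record", {
  cfg <- sim_config(n_zips = 50, seed = 3, n_events = 0)
  w <- generate_world(cfg)
  n_days <- length(seq(as.Date("2000-01-01"), as.Date("2016-12-31"),
                       by = "day"))
  expect_equal(n_days, 6210)  # 17 * 365 + 5 leap days
  expect_equal(nrow(w$covariates), 50 * n_days)
  expect_false(anyNA(w$covariates))
  expect_true(all(w$population$enrollees > 0))
  expect_true(all(w$zips$pct_black >= 0 & w$zips$pct_black <= 1))
})

test_that("covariate noise is AR(1)-autocorrelated around the seasonal cycle", {
  cfg <- sim_config(n_zips = 1, date_end = as.Date("2008-12-31"),
                    n_events = 0, seed = 5)
  w <- generate_world(cfg)
  x <- w$covariates$tmax
  doy <- as.integer(format(w$covariates$date, "%j"))
  resid <- stats::residuals(lm(x ~ sin(2 * pi * doy / 365.25) +
                                 cos(2 * pi * doy / 365.25)))
  r1 <- stats::cor(resid[-1], resid[-length(resid)])
  expect_gt(r1, 0.6)
  expect_lt(r1, 0.8)
})

test_that("event durations stay in 1..42 days and shares match the mix", {
  set.seed(1)
  d <- floodepi:::sample_duration(10000)
  expect_true(all(d >= 1 & d <= 42))
  probs <- c(moderate = 0.56, high = 0.14, extreme = 0.30)
  sev <- floodepi:::sample_severities(10000, probs)
  p_hat <- mean(sev == "moderate")
  se <- sqrt(0.56 * 0.44 / 10000)
  expect_lt(abs(p_hat - 0.56), 3 * se)

  cfg <- sim_config(n_zips = 6, date_end = as.Date("2005-12-31"),
                    n_events = 0, seed = 2)
  w <- generate_world(cfg)
  expect_equal(nrow(generate_flood_events(w, cfg)), 0)
})

test_that("events never overlap within a ZIP and keep a full lag-tail gap", {
  cfg <- sim_config(n_zips = 8, date_end = as.Date("2008-12-31"),
                    n_events = 14, seed = 21)
  w <- generate_world(cfg)
  ev <- generate_flood_events(w, cfg)
  expect_true(all(ev$frac_flooded >= 0 & ev$frac_flooded <= 1))
  expect_true(all((ev$frac_flooded > 0) == (ev$area_flooded > 0)))
  for (z in unique(ev$zip)) {
    sub <- ev[ev$zip == z, ]
    per <- do.call(rbind, lapply(split(sub, sub$event_id), function(d) {
      data.frame(start = min(d$date), end = max(d$date))
    }))
    per <- per[order(per$start), ]
    if (nrow(per) > 1) {
      gaps <- as.integer(per$start[-1] - per$end[-nrow(per)]) - 1L
      expect_true(all(gaps >= cfg$n_lags * 7L))
    }
  }
})

test_that("with no effects, counts match the configured baseline rate", {
  cfg <- sim_config(n_zips = 10, date_end = as.Date("2005-12-31"),
                    n_events = 0, causes = c(all = 60),
                    seasonal_amplitude = 0, year_trend_slope = 0,
                    covariate_effect_sizes = c(tmax = 0), dispersion = 1,
                    seed = 31)
  w <- generate_world(cfg)
  h <- generate_hospitalizations(w, generate_flood_events(w, cfg), cfg)
  pop <- w$population
  pd <- sum(vapply(seq_len(nrow(pop)), function(i) {
    yr <- pop$year[i]
    ndays <- length(seq(as.Date(paste0(yr, "-01-01")),
                        min(as.Date(paste0(yr, "-12-31")), cfg$date_end),
                        by = "day"))
    pop$enrollees[i] * ndays
  }, numeric(1)))
  total <- sum(h$counts$count)
  lambda <- pd * 60 / 1e5
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("counts are equidispersed under Poisson truth", {
  cfg <- sim_config(n_zips = 24, date_end = as.Date("2005-12-31"),
                    n_events = 0, causes = c(all = 30),
                    seasonal_amplitude = 0, year_trend_slope = 0,
                    covariate_effect_sizes = c(tmax = 0), dispersion = 1,
                    population_range = c(2000, 2000), seed = 41)
  w <- generate_world(cfg)
  h <- generate_hospitalizations(w, generate_flood_events(w, cfg), cfg)
  # reconstruct the dense cell grid (zero cells omitted from the table)
  n_cells <- 24 * length(w$dates) * 2  # two admission types
  cnt <- c(h$counts$count, rep(0L, n_cells - nrow(h$counts)))
  ratio <- stats::var(cnt) / mean(cnt)
  expect_gt(length(cnt), 1e5)
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("an injected lag-0 effect shifts exposed-day rates by that ratio", {
  cfg <- sim_config(n_zips = 10, date_end = as.Date("2007-12-31"),
                    n_events = 16, causes = c(all = 100),
                    lag_effects = list(all = c(log(1.5), 0, 0, 0, 0)),
                    seasonal_amplitude = 0, year_trend_slope = 0,
                    covariate_effect_sizes = c(tmax = 0), dispersion = 1,
                    population_range = c(3000, 3000), seed = 51)
  w <- generate_world(cfg)
  ev <- generate_flood_events(w, cfg)
  h <- generate_hospitalizations(w, ev, cfg)
  flag <- classify_exposure(ev$frac_flooded, ev$area_flooded)
  periods <- build_exposure_periods(ev[flag, ])
  lagtab <- floodepi:::lag_index_table(periods, cfg$n_lags)
  key_all <- paste(h$counts$zip, h$counts$date)
  key0 <- paste(lagtab$zip[lagtab$lag == 0], lagtab$date[lagtab$lag == 0])
  key_any <- paste(lagtab$zip, lagtab$date)
  n_exp_days <- length(key0)
  n_base_days <- 10 * length(w$dates) - length(key_any)
  y1 <- sum(h$counts$count[key_all %in% key0])
  y0 <- sum(h$counts$count[!key_all %in% key_any])
  # populations equal across zips, so day counts are proportional to rates
  rate_ratio <- (y1 / n_exp_days) / (y0 / n_base_days)
  se_log <- sqrt(1 / y1 + 1 / y0)
  expect_lt(abs(log(rate_ratio) - log(1.5)), 3 * se_log)
})

test_that("expected counts scale linearly with the population offset", {
  base <- list(n_zips = 8, date_end = as.Date("2004-12-31"), n_events = 0,
               causes = c(all = 80), seasonal_amplitude = 0,
               year_trend_slope = 0, covariate_effect_sizes = c(tmax = 0),
               dispersion = 1, seed = 61)
  cfg1 <- do.call(sim_config, c(base, list(population_range = c(1000, 1000))))
  cfg2 <- do.call(sim_config, c(base, list(population_range = c(2000, 2000))))
  t1 <- sum(generate_hospitalizations(generate_world(cfg1),
                                      generate_flood_events(
                                        generate_world(cfg1), cfg1),
                                      cfg1)$counts$count)
  t2 <- sum(generate_hospitalizations(generate_world(cfg2),
                                      generate_flood_events(
                                        generate_world(cfg2), cfg2),
                                      cfg2)$counts$count)
  expect_lt(abs(t2 / t1 - 2), 3 * 2 * sqrt(1 / t1 + 1 / t2))
})

test_that("exposure days outside the study window are rejected", {
  cfg <- sim_config(n_zips = 2, date_end = as.Date("2001-12-31"),
                    n_events = 0, causes = c(all = 10), seed = 71)
  w <- generate_world(cfg)
  bad <- data.frame(zip = "Z0001", date = as.Date("2030-01-01"),
                    event_id = "E1", frac_flooded = 0.1, area_flooded = 10,
                    severity = "moderate", cause = "heavy_rain")
  expect_error(generate_hospitalizations(w, bad, cfg), "window")
})

test_that("the truth table mirrors the configured lag effects", {
  le <- c(log(1.4), 0.1, 0, 0, 0)
  cfg <- sim_config(n_zips = 2, date_end = as.Date("2001-12-31"),
                    n_events = 0, causes = c(a = 10, b = 20),
                    lag_effects = list(a = le), seed = 81)
  w <- generate_world(cfg)
  h <- generate_hospitalizations(w, generate_flood_events(w, cfg), cfg)
  expect_equal(h$truth$true_log_rr[h$truth$cause == "a"], le)
  expect_equal(h$truth$true_log_rr[h$truth$cause == "b"], rep(0, 5))
})
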