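# Synthetic study world: ZIPs, enrollee denominators, daily covariates,
# flood events, and hospitalisation counts with known injected lag effects.
# The generator exists so that every downstream stage (exposure
# classification, matching, dataset assembly, model fitting) is testable
# end-to-end with a known truth, since real claims data are restricted.

#' Default cause categories and baseline rates
#'
#' Thirteen mutually exclusive hospitalisation cause categories with
#' baseline daily rates per 100 000 person-days, chosen so that the implied
#' annual all-cause inpatient rate (~28 per 100 person-years) and the
#' leading-cause shares (circulatory, respiratory, digestive, injury)
#' resemble an elderly fee-for-service population.
#'
#' @return named numeric vector of baseline rates per 100 000 person-days.
#' @export
default_cause_rates <- function() {
  c(circulatory = 23.0, respiratory = 10.5, digestive = 8.0,
    injury_poisoning = 7.0, neoplasms = 6.0, genitourinary = 5.0,
    musculoskeletal = 4.0, nervous_system = 3.0, mental_illness = 3.0,
    endocrine = 3.0, infectious_parasitic = 3.0, skin = 1.5, blood = 1.0)
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic world in one validated object.
#' Defaults mirror the study design: a 17-year window (2000-01-01 to
#' 2016-12-31), 72 flood events with severity mix (0.56, 0.14, 0.30) over
#' (moderate, high, extreme) and cause mix (0.81, 0.19) over (heavy rain,
#' tropical storm), 4 lag weeks, and 13 cause categories.
#'
#' @param n_zips number of ZIP zones (> 0).
#' @param date_start,date_end study window (Dates; `date_end > date_start`).
#' @param n_events number of flood events (>= 0).
#' @param causes named numeric vector: baseline daily rate per 100 000
#'   person-days for each cause label (all > 0).
#' @param lag_effects named list, cause -> numeric vector of log rate ratios
#'   of length `n_lags + 1` (index 1 = exposure period, then lag weeks).
#'   Causes omitted from the list get all-zero effects.
#' @param n_lags number of lag weeks (default 4).
#' @param seasonal_amplitude amplitude of the log-scale seasonal sinusoid in
#'   hospitalisation rates (default 0.1).
#' @param year_trend_slope log-scale secular trend per year (default 0.01).
#' @param covariate_effect_sizes named numeric vector: log rate ratio per SD
#'   of each covariate (subset of tmax, rhmax, wind, pm25, no2, o3).
#' @param dispersion overdispersion target (>= 1); counts are Poisson mixed
#'   over gamma frailties with variance `dispersion - 1` shared within
#'   (zip, week).
#' @param population_range (min, max) enrollees per ZIP.
#' @param severity_probs probabilities of (moderate, high, extreme).
#' @param flood_cause_probs probabilities of (heavy_rain, tropical_storm).
#' @param ar1_rho lag-1 autocorrelation of covariate noise (default 0.7).
#' @param emergency_frac share of admissions that are emergency (default 0.65).
#' @param seed integer RNG seed; everything downstream is deterministic in it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_zips = 50,
                       date_start = as.Date("2000-01-01"),
                       date_end = as.Date("2016-12-31"),
                       n_events = 72,
                       causes = default_cause_rates(),
                       lag_effects = list(),
                       n_lags = 4,
                       seasonal_amplitude = 0.1,
                       year_trend_slope = 0.01,
                       covariate_effect_sizes = c(tmax = 0.02, rhmax = 0.01,
                                                  pm25 = 0.02, no2 = 0.01,
                                                  o3 = 0.01),
                       dispersion = 1.5,
                       population_range = c(500, 5000),
                       severity_probs = c(moderate = 0.56, high = 0.14,
                                          extreme = 0.30),
                       flood_cause_probs = c(heavy_rain = 0.81,
                                             tropical_storm = 0.19),
                       ar1_rho = 0.7,
                       emergency_frac = 0.65,
                       seed = 1L) {
  cfg <- list(n_zips = n_zips, date_start = as.Date(date_start),
              date_end = as.Date(date_end), n_events = n_events,
              causes = causes, lag_effects = lag_effects,
              n_lags = as.integer(n_lags),
              seasonal_amplitude = seasonal_amplitude,
              year_trend_slope = year_trend_slope,
              covariate_effect_sizes = covariate_effect_sizes,
              dispersion = dispersion,
              population_range = population_range,
              severity_probs = severity_probs,
              flood_cause_probs = flood_cause_probs,
              ar1_rho = ar1_rho, emergency_frac = emergency_frac,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  err <- function(field, msg) {
    stop("invalid sim_config: field '", field, "' ", msg, call. = FALSE)
  }
  if (!is.numeric(cfg$n_zips) || cfg$n_zips < 1) err("n_zips", "must be >= 1")
  if (!inherits(cfg$date_start, "Date") || !inherits(cfg$date_end, "Date") ||
      is.na(cfg$date_start) || is.na(cfg$date_end)) {
    err("date_start/date_end", "must be valid Dates")
  }
  if (cfg$date_end <= cfg$date_start) err("date_end", "must be > date_start")
  if (!is.numeric(cfg$n_events) || cfg$n_events < 0) {
    err("n_events", "must be >= 0")
  }
  if (length(cfg$causes) < 1 || is.null(names(cfg$causes)) ||
      any(!nzchar(names(cfg$causes)))) {
    err("causes", "must be a named vector of baseline rates")
  }
  if (any(cfg$causes <= 0)) err("causes", "baseline rates must all be > 0")
  if (cfg$n_lags < 0) err("n_lags", "must be >= 0")
  if (length(cfg$lag_effects) > 0) {
    if (is.null(names(cfg$lag_effects))) {
      err("lag_effects", "must be a named list keyed by cause")
    }
    bad <- names(cfg$lag_effects)[!names(cfg$lag_effects) %in%
                                    names(cfg$causes)]
    if (length(bad)) err("lag_effects", paste("has unknown cause(s):",
                                              paste(bad, collapse = ", ")))
    len_ok <- vapply(cfg$lag_effects, length, integer(1)) == cfg$n_lags + 1L
    if (!all(len_ok)) {
      err("lag_effects", paste0("vectors must have length n_lags + 1 = ",
                                cfg$n_lags + 1L))
    }
  }
  if (cfg$dispersion < 1) err("dispersion", "must be >= 1")
  if (length(cfg$population_range) != 2 ||
      any(cfg$population_range <= 0) ||
      cfg$population_range[1] > cfg$population_range[2]) {
    err("population_range", "must be a positive (min, max) pair")
  }
  if (length(cfg$severity_probs) != 3 || any(cfg$severity_probs < 0) ||
      abs(sum(cfg$severity_probs) - 1) > 1e-8) {
    err("severity_probs", "must be 3 probabilities summing to 1")
  }
  if (length(cfg$flood_cause_probs) != 2 || any(cfg$flood_cause_probs < 0) ||
      abs(sum(cfg$flood_cause_probs) - 1) > 1e-8) {
    err("flood_cause_probs", "must be 2 probabilities summing to 1")
  }
  if (cfg$ar1_rho < 0 || cfg$ar1_rho >= 1) err("ar1_rho", "must be in [0, 1)")
  if (cfg$emergency_frac <= 0 || cfg$emergency_frac >= 1) {
    err("emergency_frac", "must be in (0, 1)")
  }
  if (is.na(cfg$seed)) err("seed", "must be an integer")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_zips, "ZIPs,",
      format(x$date_start), "to", format(x$date_end), "\n",
      x$n_events, "flood events,", length(x$causes), "causes,",
      x$n_lags, "lag weeks, dispersion", x$dispersion,
      ", seed", x$seed, "\n")
  invisible(x)
}

COVARIATE_NAMES <- c("tmax", "rhmax", "wind", "pm25", "no2", "o3")

# seasonal sinusoid + AR(1) noise for one zip-series
seasonal_ar1 <- function(doy, mean_level, amp, noise_sd, rho, phase = 105) {
  n <- length(doy)
  eps <- stats::rnorm(n, 0, noise_sd * sqrt(1 - rho^2))
  noise <- as.numeric(stats::filter(eps, rho, method = "recursive"))
  mean_level + amp * sin(2 * pi * (doy - phase) / 365.25) + noise
}

#' Generate the synthetic study world
#'
#' Builds ZIP identifiers and surface areas, ZIP-year enrollee counts,
#' daily weather and pollution covariates (seasonal sinusoid plus AR(1)
#' noise, lag-1 correlation `ar1_rho`), and once-per-ZIP census covariates
#' (% Black residents, median income, poverty rate). Fully deterministic
#' given `config$seed`.
#'
#' @param config a [sim_config()].
#' @return object of class `synthetic_world`: list with `zips` (zip, area,
#'   pct_black, median_income, poverty_rate), `population` (zip, year,
#'   enrollees), `covariates` (data.table: zip, date, tmax, rhmax, wind,
#'   pm25, no2, o3), `dates`, and the `config`.
#' @export
generate_world <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  dates <- seq(config$date_start, config$date_end, by = "day")
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  doy <- as.integer(format(dates, "%j"))
  zip_ids <- sprintf("Z%04d", seq_len(config$n_zips))

  zips <- data.frame(
    zip = zip_ids,
    area_sqmi = stats::runif(config$n_zips, 30, 150),
    pct_black = stats::rbeta(config$n_zips, 1.2, 6),
    median_income = round(exp(stats::rnorm(config$n_zips,
                                           log(45000), 0.35))),
    poverty_rate = stats::rbeta(config$n_zips, 2, 10),
    stringsAsFactors = FALSE
  )

  base_pop <- round(stats::runif(config$n_zips, config$population_range[1],
                                 config$population_range[2]))
  # mild zip-specific enrolment drift across years
  drift <- stats::rnorm(config$n_zips, 0.01, 0.01)
  population <- data.table::CJ(zip = zip_ids, year = years, sorted = TRUE)
  population[, `:=`(enrollees = {
    i <- match(zip, zip_ids)
    pmax(1L, as.integer(round(base_pop[i] *
                                exp(drift[i] * (year - years[1])))))
  })]

  cov_list <- vector("list", config$n_zips)
  for (i in seq_len(config$n_zips)) {
    cov_list[[i]] <- data.table::data.table(
      zip = zip_ids[i],
      date = dates,
      tmax = seasonal_ar1(doy, 18 + stats::rnorm(1, 0, 3), 11, 3,
                          config$ar1_rho),
      rhmax = pmin(100, pmax(5, seasonal_ar1(doy, 70 + stats::rnorm(1, 0, 4),
                                             8, 8, config$ar1_rho,
                                             phase = 200))),
      wind = pmax(0.1, seasonal_ar1(doy, 4 + stats::rnorm(1, 0, 0.5),
                                    0.8, 1.2, config$ar1_rho, phase = 15)),
      pm25 = pmax(0.5, seasonal_ar1(doy, 9 + stats::rnorm(1, 0, 1.5),
                                    2.5, 2.5, config$ar1_rho, phase = 200)),
      no2 = pmax(0.5, seasonal_ar1(doy, 12 + stats::rnorm(1, 0, 2),
                                   3, 3, config$ar1_rho, phase = 15)),
      o3 = pmax(1, seasonal_ar1(doy, 38 + stats::rnorm(1, 0, 3),
                                8, 4, config$ar1_rho, phase = 105))
    )
  }
  covariates <- data.table::rbindlist(cov_list)
  data.table::setkeyv(covariates, c("zip", "date"))

  world <- list(zips = zips, population = as.data.frame(population),
                covariates = covariates, dates = dates, years = years,
                config = config)
  class(world) <- "synthetic_world"
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", nrow(x$zips), "ZIPs,",
      length(x$dates), "days (", format(min(x$dates)), "to",
      format(max(x$dates)), ")\n")
  invisible(x)
}

sample_severities <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

sample_flood_causes <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# duration sampler: discretised lognormal resampled into [1, 42] days
sample_duration <- function(n, meanlog = log(4), sdlog = 0.9,
                            dmin = 1L, dmax = 42L) {
  out <- integer(0)
  while (length(out) < n) {
    d <- as.integer(round(stats::rlnorm(n, meanlog, sdlog)))
    d <- d[d >= dmin & d <= dmax]
    out <- c(out, d)
  }
  out[seq_len(n)]
}

#' Generate flood events as ZIP-day exposure records
#'
#' Samples `n_events` flood events: a start date, a duration from a
#' discretised lognormal truncated to 1..42 days, a contiguous block of
#' ZIPs, per-ZIP flooded fractions (beta-distributed, so some ZIP-days fall
#' under the exposure thresholds), a severity label and a flood-cause
#' label. Within a ZIP, events are kept at least `n_lags * 7` days apart
#' (resampled on collision) so every day has an unambiguous lag assignment.
#'
#' @param world a `synthetic_world`.
#' @param config the same [sim_config()] used to build it.
#' @return data.frame of ZIP-day exposures: `zip`, `date`, `event_id`,
#'   `frac_flooded`, `area_flooded`, `severity`, `cause`.
#' @export
generate_flood_events <- function(world, config) {
  stopifnot(inherits(world, "synthetic_world"))
  validate_sim_config(config)
  set.seed(config$seed + 1000L)
  empty <- data.frame(zip = character(0), date = as.Date(character(0)),
                      event_id = character(0), frac_flooded = numeric(0),
                      area_flooded = numeric(0), severity = character(0),
                      cause = character(0), stringsAsFactors = FALSE)
  if (config$n_events == 0L) return(empty)

  n_days <- length(world$dates)
  tail_days <- config$n_lags * 7L
  # per-zip occupied intervals [start_idx, end_idx + tail]
  occupied <- vector("list", config$n_zips)
  recs <- vector("list", config$n_events)
  for (e in seq_len(config$n_events)) {
    placed <- FALSE
    for (attempt in 1:500) {
      dur <- sample_duration(1L)
      start_idx <- sample.int(n_days - dur - tail_days + 1L, 1L)
      end_idx <- start_idx + dur - 1L
      n_block <- min(config$n_zips, 1L + stats::rpois(1L, 3))
      z0 <- sample.int(config$n_zips - n_block + 1L, 1L)
      zidx <- z0:(z0 + n_block - 1L)
      lo <- start_idx - tail_days  # new event's window + existing tails
      hi <- end_idx + tail_days
      clash <- any(vapply(zidx, function(z) {
        occ <- occupied[[z]]
        !is.null(occ) && any(occ[, 1] <= hi & occ[, 2] >= lo)
      }, logical(1)))
      if (!clash) {
        for (z in zidx) {
          occupied[[z]] <- rbind(occupied[[z]], c(start_idx, end_idx))
        }
        sev <- sample_severities(1L, config$severity_probs)
        cse <- sample_flood_causes(1L, config$flood_cause_probs)
        frac <- stats::rbeta(n_block, 0.8, 8)
        zip_ids <- world$zips$zip[zidx]
        area <- frac * world$zips$area_sqmi[zidx]
        grid <- expand.grid(zi = seq_len(n_block),
                            di = start_idx:end_idx)
        recs[[e]] <- data.frame(
          zip = zip_ids[grid$zi],
          date = world$dates[grid$di],
          event_id = sprintf("E%03d", e),
          frac_flooded = frac[grid$zi],
          area_flooded = area[grid$zi],
          severity = sev,
          cause = cse,
          stringsAsFactors = FALSE
        )
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place flood event ", e,
           " without overlap; reduce n_events or enlarge the window")
    }
  }
  out <- do.call(rbind, recs)
  out <- out[order(out$zip, out$date), ]
  rownames(out) <- NULL
  out
}

# lag index (0..n_lags) of each (zip, date) relative to exposure periods,
# NA when outside every exposure/lag window
lag_index_table <- function(periods, n_lags) {
  if (nrow(periods) == 0L) {
    return(data.table::data.table(zip = character(0),
                                  date = as.Date(character(0)),
                                  lag = integer(0)))
  }
  pieces <- lapply(seq_len(nrow(periods)), function(i) {
    s <- as.Date(periods$start_date[i]); e <- as.Date(periods$end_date[i])
    d0 <- seq(s, e, by = "day")
    lag <- rep(0L, length(d0))
    if (n_lags > 0L) {
      dl <- seq(e + 1L, e + 7L * n_lags, by = "day")
      d0 <- c(d0, dl)
      lag <- c(lag, rep(1:n_lags, each = 7L))
    }
    data.table::data.table(zip = periods$zip[i], date = d0, lag = lag)
  })
  tab <- data.table::rbindlist(pieces)
  # exposure days take precedence over any lag day (cannot happen with the
  # generator's spacing, but guards hand-built inputs)
  tab <- tab[order(zip, date, lag)]
  unique(tab, by = c("zip", "date"))
}

#' Generate hospitalisation counts with injected flood effects
#'
#' For each (zip, day, cause), the expected count is
#' `enrollees * exp(log(base_rate) + seasonal + trend + covariate effects +
#' lag effect)`, where the lag effect `lag_effects[[cause]][l + 1]` applies
#' when the day lies in lag window `l` of a flood exposure (l = 0 is the
#' exposure period itself; exposure days are classified with
#' [classify_exposure()]). Counts are Poisson draws scaled by a gamma
#' frailty with mean 1 and variance `dispersion - 1` shared within
#' (zip, week), which induces quasi-Poisson overdispersion. Counts are
#' split into emergency and non-emergency admissions by Poisson thinning.
#'
#' @param world a `synthetic_world`.
#' @param exposures ZIP-day exposure table from [generate_flood_events()]
#'   (may be empty).
#' @param config the [sim_config()].
#' @return list with `counts` (data.table: zip, date, cause,
#'   admission_type, count; zero cells omitted) and `truth` (data.frame:
#'   cause, lag, true_log_rr).
#' @export
generate_hospitalizations <- function(world, exposures, config) {
  stopifnot(inherits(world, "synthetic_world"))
  validate_sim_config(config)
  if (nrow(exposures) > 0) {
    d <- as.Date(exposures$date)
    if (any(d < config$date_start | d > config$date_end)) {
      stop("exposure days outside the study window")
    }
  }
  set.seed(config$seed + 2000L)

  # exposed zip-days per the exposure rule, collapsed to periods
  if (nrow(exposures) > 0) {
    flag <- classify_exposure(exposures$frac_flooded, exposures$area_flooded)
    periods <- build_exposure_periods(exposures[flag, , drop = FALSE])
  } else {
    periods <- build_exposure_periods(exposures)
  }
  lagtab <- lag_index_table(periods, config$n_lags)

  cov <- data.table::copy(world$covariates)
  # standardise covariates so configured effects are per SD
  eff <- config$covariate_effect_sizes
  cov_eff <- rep(0, nrow(cov))
  for (v in names(eff)) {
    if (!v %in% COVARIATE_NAMES) {
      stop("unknown covariate in covariate_effect_sizes: ", v)
    }
    x <- cov[[v]]
    cov_eff <- cov_eff + eff[[v]] * (x - mean(x)) / stats::sd(x)
  }
  cells <- data.table::data.table(zip = cov$zip, date = cov$date,
                                  cov_eff = cov_eff)
  cells[, year := data.table::year(date)]
  cells[, doy := data.table::yday(date)]
  pop <- data.table::as.data.table(world$population)
  cells <- pop[cells, on = c("zip", "year")]
  year0 <- world$years[1]
  cells[, base_lp := log(enrollees) +
          config$seasonal_amplitude * sin(2 * pi * (doy - 30) / 365.25) +
          config$year_trend_slope * (year - year0)]
  if (nrow(lagtab) > 0) {
    cells <- lagtab[cells, on = c("zip", "date")]
  } else {
    cells[, lag := NA_integer_]
  }

  # gamma frailty shared within (zip, week-of-study)
  v <- config$dispersion - 1
  cells[, week_id := as.integer(date - config$date_start) %/% 7L]
  if (v > 0) {
    fr <- unique(cells[, c("zip", "week_id")])
    fr[, g := stats::rgamma(.N, shape = 1 / v, rate = 1 / v)]
    cells <- fr[cells, on = c("zip", "week_id")]
  } else {
    cells[, g := 1]
  }

  p_em <- config$emergency_frac
  out <- vector("list", length(config$causes))
  for (k in seq_along(config$causes)) {
    cz <- names(config$causes)[k]
    le <- config$lag_effects[[cz]]
    if (is.null(le)) le <- rep(0, config$n_lags + 1L)
    lag_term <- ifelse(is.na(cells$lag), 0, le[cells$lag + 1L])
    mu <- cells$g * exp(cells$base_lp + log(config$causes[[k]] / 1e5) +
                          cells$cov_eff + lag_term)
    n_em <- stats::rpois(length(mu), mu * p_em)
    n_ne <- stats::rpois(length(mu), mu * (1 - p_em))
    keep_e <- n_em > 0L
    keep_n <- n_ne > 0L
    out[[k]] <- data.table::rbindlist(list(
      data.table::data.table(zip = cells$zip[keep_e],
                             date = cells$date[keep_e], cause = cz,
                             admission_type = "emergency",
                             count = n_em[keep_e]),
      data.table::data.table(zip = cells$zip[keep_n],
                             date = cells$date[keep_n], cause = cz,
                             admission_type = "non_emergency",
                             count = n_ne[keep_n])
    ))
  }
  counts <- data.table::rbindlist(out)
  data.table::setkeyv(counts, c("zip", "date", "cause"))

  truth <- do.call(rbind, lapply(names(config$causes), function(cz) {
    le <- config$lag_effects[[cz]]
    if (is.null(le)) le <- rep(0, config$n_lags + 1L)
    data.frame(cause = cz, lag = 0:config$n_lags, true_log_rr = le,
               stringsAsFactors = FALSE)
  }))
  list(counts = counts, truth = truth)
}

#' Simulate a complete flood-health study
#'
#' Convenience wrapper: world, flood events, hospitalisation counts and the
#' truth table in one call; optionally writes the five input CSVs plus the
#' truth CSV to a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory for CSV output.
#' @return list with `world`, `exposures`, `counts`, `truth`, `config`.
#' @export
simulate_flood_study <- function(config, out_dir = NULL) {
  world <- generate_world(config)
  exposures <- generate_flood_events(world, config)
  hosp <- generate_hospitalizations(world, exposures, config)
  res <- list(world = world, exposures = exposures, counts = hosp$counts,
              truth = hosp$truth, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) {
      data.table::fwrite(data.table::as.data.table(x),
                         file.path(out_dir, f))
    }
    w(exposures, "exposures.csv")
    w(hosp$counts, "counts.csv")
    w(world$covariates, "covariates.csv")
    w(world$population, "population.csv")
    w(world$zips, "census.csv")
    w(hosp$truth, "truth.csv")
  }
  res
}
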