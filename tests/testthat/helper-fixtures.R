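# Shared fixtures: random conditional-Poisson datasets, hand-built strata,
# and the reduced-scale replicate design used for calibration checks.

# random small conditional-Poisson dataset with the analytical-row layout
make_cqp_fixture <- function(S, n_lags = 2L, p_extra = 2L,
                             beta = NULL, alpha_mean = -6) {
  rows <- S * 3L * (n_lags + 1L)
  arm <- rep(rep(c("exposed", "control_1", "control_2"),
                 each = n_lags + 1L), S)
  lag <- rep(0:n_lags, 3L * S)
  Xl <- sapply(0:n_lags, function(l) as.numeric(arm == "exposed" & lag == l))
  colnames(Xl) <- paste0("exp_lag", 0:n_lags)
  X <- Xl
  if (p_extra > 0) {
    Xe <- matrix(stats::rnorm(rows * p_extra), rows, p_extra,
                 dimnames = list(NULL, paste0("z", seq_len(p_extra))))
    X <- cbind(Xl, Xe)
  }
  stratum <- factor(rep(seq_len(S), each = 3L * (n_lags + 1L)))
  off <- log(stats::runif(rows, 500, 5000))
  if (is.null(beta)) {
    beta <- c(stats::runif(n_lags + 1L, -0.3, 0.4),
              stats::rnorm(p_extra, 0, 0.1))
  }
  alpha <- stats::rnorm(S, alpha_mean, 0.3)
  mu <- exp(alpha[as.integer(stratum)] + drop(X %*% beta) + off)
  y <- stats::rpois(rows, mu)
  list(X = X, y = y, offset = off, stratum = stratum,
       lag_cols = colnames(Xl), cause = "fixture", n_lags = n_lags,
       true_beta = beta)
}

# one hand-written matched stratum row in the build_strata layout
make_stratum_row <- function(zip = "Z0001", exposed_start, exposed_end,
                             c1_start, c2_start, n_lags = 4L,
                             severity = "moderate", cause = "heavy_rain") {
  exposed_start <- as.Date(exposed_start)
  exposed_end <- as.Date(exposed_end)
  dur <- as.integer(exposed_end - exposed_start) + 1L
  c1 <- as.Date(c1_start); c2 <- as.Date(c2_start)
  data.frame(stratum_id = paste0(zip, "_", format(exposed_start, "%Y%m%d")),
             zip = zip, exposed_start = exposed_start,
             exposed_end = exposed_end, duration_days = dur,
             severity = severity, cause = cause,
             control1_start = c1, control1_end = c1 + dur - 1L,
             control1_year = as.integer(format(c1, "%Y")),
             control2_start = c2, control2_end = c2 + dur - 1L,
             control2_year = as.integer(format(c2, "%Y")),
             n_lags = as.integer(n_lags), stringsAsFactors = FALSE)
}

as_matched_strata <- function(df) {
  out <- list(strata = df,
              attrition = data.frame(stratum_id = character(0),
                                     zip = character(0),
                                     reason = character(0)),
              n_periods = nrow(df), n_matched = nrow(df))
  class(out) <- "matched_strata"
  out
}

# reduced-scale study design for the 200-replicate calibration checks:
# 10 ZIPs over 6 years, 10 events, one all-cause outcome, Poisson truth
# (dispersion 1, no covariate confounding) so CI calibration is tested
# under correct specification
replicate_config <- function(seed, lag_effects_all = rep(0, 5)) {
  sim_config(n_zips = 10, date_start = as.Date("2000-01-01"),
             date_end = as.Date("2005-12-31"), n_events = 10,
             causes = c(all = 60),
             lag_effects = list(all = lag_effects_all),
             dispersion = 1, covariate_effect_sizes = c(tmax = 0),
             seed = seed)
}

recovery_lag_profile <- c(log(1.5), log(1.3), log(1.2), log(1.1), 0)

# fit one replicate; returns per-lag estimate/se or NULL if matching fails
fit_replicate <- function(seed, lag_effects_all = rep(0, 5)) {
  cfg <- replicate_config(seed, lag_effects_all)
  res <- tryCatch(run_flood_pipeline(cfg, causes = "all"),
                  error = function(e) NULL)
  if (is.null(res)) return(NULL)
  fit <- res$fits$all
  if (!fit$converged) return(NULL)
  data.frame(lag = 0:4, est = unname(fit$beta[fit$lag_cols]),
             se = unname(sqrt(diag(fit$vcov)[fit$lag_cols])))
}
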