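# End-to-end pipeline: simulate (or accept) inputs, classify exposure,
# build periods, match controls, assemble, fit, report effects.

#' Run the full flood-hospitalisation analysis on synthetic data
#'
#' Chains every stage: [simulate_flood_study()], exposure classification
#' and period construction, rain/storm cause filtering, control matching,
#' dataset assembly, conditional quasi-Poisson fitting, and effect
#' reporting, for one or more causes. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param causes cause labels to analyse (default: all configured causes).
#' @param alpha,m CI parameters passed to [lag_effects()] /
#'   [mean_effect()].
#' @param cause_filter allowed flood causes (default rain/storm rule);
#'   `NULL` disables the filter.
#' @param cov_names covariates to adjust for.
#' @param frac_threshold,area_threshold exposure thresholds, see
#'   [classify_exposure()].
#' @return list with `effects` (tidy per-lag + mean table across causes),
#'   `fits` (named list of `cqp_fit`), `strata`, `periods`, `sim` (the
#'   simulated tables), `truth`.
#' @export
run_flood_pipeline <- function(config, causes = NULL, alpha = 0.05,
                               m = NULL,
                               cause_filter = c("heavy_rain",
                                                "tropical_storm"),
                               cov_names = COVARIATE_NAMES,
                               frac_threshold = 0.005,
                               area_threshold = 5.0) {
  sim <- simulate_flood_study(config)
  if (is.null(causes)) causes <- names(config$causes)

  flag <- classify_exposure(sim$exposures$frac_flooded,
                            sim$exposures$area_flooded,
                            frac_threshold, area_threshold)
  exposed_days <- sim$exposures[flag, , drop = FALSE]
  periods <- build_exposure_periods(exposed_days)
  if (!is.null(cause_filter)) {
    periods <- filter_periods_by_cause(periods, cause_filter)
  }
  window <- c(config$date_start, config$date_end)
  strata <- build_strata(periods, exposed_days[, c("zip", "date")],
                         window, n_lags = config$n_lags)
  if (strata$n_matched == 0L) stop("no exposure period could be matched")

  fits <- list()
  effects <- list()
  for (cz in causes) {
    ds <- build_analytical_dataset(strata, sim$counts,
                                   sim$world$covariates,
                                   sim$world$population, cz,
                                   cov_names = cov_names)
    fit <- fit_conditional_quasipoisson(ds)
    le <- lag_effects(fit, alpha = alpha, m = m)
    le$lag_label <- as.character(le$lag)
    effects[[cz]] <- rbind(le, mean_effect(fit, alpha = alpha, m = m))
    fits[[cz]] <- fit
  }
  eff <- do.call(rbind, effects)
  rownames(eff) <- NULL
  list(effects = eff, fits = fits, strata = strata, periods = periods,
       sim = sim, truth = sim$truth)
}
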