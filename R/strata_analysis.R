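# Stratified analyses: flood severity, season, admission type, and
# ZIP-level demographic/socioeconomic splits; plus the subcause inclusion
# rule.

#' Median split of a ZIP-level covariate
#'
#' Labels ZIPs strictly above the median as `"higher"`, all others
#' `"lower"`. An explicit `threshold` overrides the median. The threshold
#' used is attached as an attribute for logging.
#'
#' @param zip_values named numeric vector (names = ZIP ids).
#' @param threshold optional explicit cut value.
#' @return named character vector of `"higher"`/`"lower"`, attribute
#'   `threshold`.
#' @export
median_split <- function(zip_values, threshold = NULL) {
  if (length(zip_values) < 2L && is.null(threshold)) {
    stop("need at least 2 ZIPs for a median split")
  }
  if (is.null(threshold)) {
    if (length(unique(zip_values)) == 1L) {
      stop("all ZIP values identical; median split undefined")
    }
    threshold <- stats::median(zip_values)
  }
  out <- ifelse(zip_values > threshold, "higher", "lower")
  names(out) <- names(zip_values)
  attr(out, "threshold") <- threshold
  out
}

#' Stratifier specification
#'
#' Declarative description of one stratified analysis. Three kinds:
#' `stratum_level` rules partition whole matched strata by their own
#' metadata (severity, season); `zip_level` rules partition strata by a
#' ZIP-level covariate split; `row_level` rules re-aggregate the outcome
#' under a filter (admission type) and re-fit on all strata.
#'
#' @param name one of `"severity"`, `"season"`, `"admission"`,
#'   `"pct_black"`, `"median_income"`, `"poverty_rate"`.
#' @param threshold optional explicit cut for zip_level splits.
#' @param warm_months months counted as the warm season (default
#'   April-September).
#' @return object of class `stratifier`.
#' @export
stratifier <- function(name = c("severity", "season", "admission",
                                "pct_black", "median_income",
                                "poverty_rate"),
                       threshold = NULL, warm_months = 4:9) {
  name <- match.arg(name)
  kind <- switch(name,
                 severity = "stratum_level", season = "stratum_level",
                 admission = "row_level",
                 "zip_level")
  out <- list(name = name, kind = kind, threshold = threshold,
              warm_months = warm_months)
  class(out) <- "stratifier"
  out
}

#' Partition matched strata for a stratified analysis
#'
#' For `stratum_level` and `zip_level` stratifiers, splits the
#' `matched_strata` object into named subsets (whole strata are never
#' divided, and the union of the subsets is the input). For the
#' `row_level` admission stratifier, returns the full strata once per
#' admission type together with the count filter to apply during
#' assembly.
#'
#' @param strata a `matched_strata` object.
#' @param strat a [stratifier()] (or its name as a string).
#' @param census data.frame with `zip` and ZIP-level covariate columns
#'   (required for zip_level stratifiers).
#' @return named list; each element is a list with `strata` (a
#'   `matched_strata`) and `admission_filter` (`NULL` except for the
#'   admission stratifier).
#' @export
stratify_strata <- function(strata, strat, census = NULL) {
  if (is.character(strat)) strat <- stratifier(strat)
  stopifnot(inherits(strata, "matched_strata"))
  df <- strata$strata
  subset_of <- function(keep) {
    out <- list(strata = df[keep, , drop = FALSE],
                attrition = strata$attrition,
                n_periods = strata$n_periods, n_matched = sum(keep))
    class(out) <- "matched_strata"
    out
  }
  if (strat$name == "severity") {
    lvl <- ifelse(df$severity == "moderate", "moderate", "high_extreme")
    if (anyNA(lvl)) stop("severity metadata missing on some strata")
    groups <- split(seq_len(nrow(df)), lvl)
    return(lapply(groups, function(ix) {
      list(strata = subset_of(seq_len(nrow(df)) %in% ix),
           admission_filter = NULL)
    }))
  }
  if (strat$name == "season") {
    mo <- as.integer(format(as.Date(df$exposed_start), "%m"))
    lvl <- ifelse(mo %in% strat$warm_months, "warm", "cold")
    groups <- split(seq_len(nrow(df)), lvl)
    return(lapply(groups, function(ix) {
      list(strata = subset_of(seq_len(nrow(df)) %in% ix),
           admission_filter = NULL)
    }))
  }
  if (strat$name == "admission") {
    return(list(
      emergency = list(strata = strata, admission_filter = "emergency"),
      non_emergency = list(strata = strata,
                           admission_filter = "non_emergency")))
  }
  # zip_level: split over exposed ZIPs (the analysis population)
  if (is.null(census)) stop("zip_level stratifier needs a census table")
  if (!strat$name %in% names(census)) {
    stop("census table lacks column '", strat$name, "'")
  }
  vals <- census[[strat$name]][match(unique(df$zip), census$zip)]
  if (anyNA(vals)) stop("census values missing for some exposed ZIPs")
  names(vals) <- unique(df$zip)
  lab <- median_split(vals, threshold = strat$threshold)
  lvl <- lab[df$zip]
  groups <- split(seq_len(nrow(df)), lvl)
  lapply(groups, function(ix) {
    list(strata = subset_of(seq_len(nrow(df)) %in% ix),
         admission_filter = NULL)
  })
}

#' Run a stratified analysis
#'
#' Applies [stratify_strata()], then for each stratum level assembles the
#' analytical dataset, fits the conditional quasi-Poisson model and
#' collects per-lag and mean effects into one tidy table. Levels with no
#' matched strata (or failing fits) are skipped with a warning.
#'
#' @param strata a `matched_strata` object.
#' @param counts,covariates,population,census input tables.
#' @param cause cause label to analyse.
#' @param strat a [stratifier()] or its name.
#' @param alpha,m CI parameters, see [lag_effects()].
#' @param ... passed to [build_analytical_dataset()].
#' @return data.frame: `stratifier`, `stratum`, `cause`, `lag`,
#'   `lag_label`, `pct_change`, `ci_low`, `ci_high`, ...
#' @export
run_stratified <- function(strata, counts, covariates, population,
                           census = NULL, cause, strat, alpha = 0.05,
                           m = NULL, ...) {
  if (is.character(strat)) strat <- stratifier(strat)
  parts <- stratify_strata(strata, strat, census)
  out <- list()
  for (lev in names(parts)) {
    part <- parts[[lev]]
    if (part$strata$n_matched == 0L) {
      warning("stratum '", lev, "' has no matched strata; skipped")
      next
    }
    res <- tryCatch({
      ds <- build_analytical_dataset(part$strata, counts, covariates,
                                     population, cause,
                                     admission_filter =
                                       part$admission_filter, ...)
      fit <- fit_conditional_quasipoisson(ds)
      le <- lag_effects(fit, alpha = alpha, m = m)
      le$lag_label <- as.character(le$lag)
      rbind(le, mean_effect(fit, alpha = alpha, m = m))
    }, error = function(e) {
      warning("stratum '", lev, "' skipped: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) next
    res$stratifier <- strat$name
    res$stratum <- lev
    out[[lev]] <- res
  }
  if (!length(out)) stop("no stratum produced a fit")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  front <- c("stratifier", "stratum", "cause", "lag", "lag_label")
  res[, c(front, setdiff(names(res), front))]
}

#' Subcause inclusion rule
#'
#' Keeps only outcome groups whose total count in the study sample reaches
#' `min_total` (default 20 000) — the inclusion rule for subcause
#' analyses. Works on any grouping column.
#'
#' @param counts count table with a `count` column.
#' @param group name of the grouping column (default `"cause"`).
#' @param min_total inclusion threshold (default 20000).
#' @return list: `included` (labels meeting the rule), `totals` (named
#'   totals), `counts` (filtered table).
#' @export
filter_subcauses <- function(counts, group = "cause", min_total = 20000) {
  tot <- tapply(counts$count, counts[[group]], sum)
  included <- names(tot)[tot >= min_total]
  list(included = included, totals = tot,
       counts = counts[counts[[group]] %in% included, , drop = FALSE])
}

#' Apply a diagnosis-code to cause mapping
#'
#' Turns line-level records (one row per admission with a diagnosis code)
#' into the ZIP-day-cause count table, applying a user-supplied two-column
#' mapping verbatim. Records whose code is absent from the mapping are
#' dropped with a message.
#'
#' @param records data.frame with `zip`, `date`, `code` and optionally
#'   `admission_type`.
#' @param mapping data.frame with columns `code`, `cause`.
#' @return count table: `zip`, `date`, `cause`, `admission_type`, `count`.
#' @export
map_diagnosis_codes <- function(records, mapping) {
  stopifnot(all(c("code", "cause") %in% names(mapping)))
  cause <- mapping$cause[match(records$code, mapping$code)]
  drop_n <- sum(is.na(cause))
  if (drop_n > 0) {
    message(drop_n, " record(s) with unmapped diagnosis codes dropped")
  }
  rec <- records[!is.na(cause), , drop = FALSE]
  rec$cause <- cause[!is.na(cause)]
  if (is.null(rec$admission_type)) rec$admission_type <- "unknown"
  dt <- data.table::as.data.table(rec)
  out <- dt[, .(count = .N), by = .(zip, date, cause, admission_type)]
  as.data.frame(out)
}
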