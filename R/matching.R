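# Self-matched control selection: each flood exposure period is matched to
# two non-flooded control windows in the same ZIP and days of the year, in
# other years of the study window. The matched triplet (exposed + 2
# controls) is the stratum that conditions the model.

# shift a date's month-day to another year; Feb 29 maps to Feb 28 in
# non-leap years
shift_to_year <- function(date, year) {
  date <- as.Date(date)
  m <- as.integer(format(date, "%m"))
  d <- as.integer(format(date, "%d"))
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  if (m == 2L && d == 29L && !leap) d <- 28L
  as.Date(sprintf("%04d-%02d-%02d", year, m, d))
}

# exposure calendar lookup: any exposed day for `zip` in [from, to]?
any_exposed_in <- function(calendar_keys, zip, from, to) {
  if (to < from) return(FALSE)
  days <- seq(from, to, by = "day")
  any(paste(zip, days) %in% calendar_keys)
}

make_calendar_keys <- function(exposure_calendar) {
  if (nrow(exposure_calendar) == 0L) return(character(0))
  paste(exposure_calendar$zip, as.Date(exposure_calendar$date))
}

#' Candidate control windows for an exposure period
#'
#' For every study-window year other than the exposure year, shifts the
#' exposure period's start month-day to that year (Feb 29 maps to Feb 28 in
#' non-leap years) and keeps the duration in calendar days. A candidate is
#' retained when (a) the window plus its `n_lags * 7`-day lag tail lies
#' inside the study window and (b) no day of that extended range is a
#' flood-exposed day for the same ZIP.
#'
#' @param period one-row data.frame (or list) with `zip`, `start_date`,
#'   `end_date`.
#' @param exposure_calendar data.frame of exposed ZIP-days (`zip`, `date`),
#'   typically [expand_periods_to_days()] of all exposure periods.
#' @param window length-2 Date vector: study window (start, end).
#' @param n_lags number of trailing lag weeks that must also be flood-free
#'   and inside the window (default 4). Set `check_tail = FALSE` to require
#'   only the control window itself to be flood-free.
#' @param check_tail if `TRUE` (default) condition (b) covers the lag tail.
#' @return data.frame of candidates: `year`, `start_date`, `end_date`.
#' @export
candidate_controls <- function(period, exposure_calendar, window,
                               n_lags = 4L, check_tail = TRUE) {
  start <- as.Date(period$start_date[1])
  end <- as.Date(period$end_date[1])
  zip <- period$zip[1]
  dur <- as.integer(end - start) + 1L
  exp_year <- as.integer(format(start, "%Y"))
  keys <- make_calendar_keys(exposure_calendar)
  years <- seq(as.integer(format(as.Date(window[1]), "%Y")),
               as.integer(format(as.Date(window[2]), "%Y")))
  tail_days <- if (check_tail) n_lags * 7L else 0L
  cand <- lapply(setdiff(years, exp_year), function(y) {
    cs <- shift_to_year(start, y)
    ce <- cs + dur - 1L
    lag_end <- ce + n_lags * 7L
    if (cs < as.Date(window[1]) || lag_end > as.Date(window[2])) return(NULL)
    scan_end <- ce + tail_days
    if (any_exposed_in(keys, zip, cs, scan_end)) return(NULL)
    data.frame(year = y, start_date = cs, end_date = ce)
  })
  out <- do.call(rbind, cand)
  if (is.null(out)) {
    out <- data.frame(year = integer(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)))
  }
  out
}

#' Select two control windows from the candidates
#'
#' Default policy `"nearest_balanced"`: the nearest eligible year before
#' the exposure year and the nearest after; when one side has no
#' candidate, the two nearest years on the other side. Policy `"random_2"`
#' draws two candidates uniformly (under the caller's RNG state) for
#' sensitivity analyses. Deterministic given candidates and policy
#' (and RNG seed for `"random_2"`).
#'
#' @param candidates data.frame from [candidate_controls()].
#' @param exposure_year integer year of the exposure period's start.
#' @param policy `"nearest_balanced"` or `"random_2"`.
#' @return data.frame of up to 2 selected rows of `candidates`, ordered by
#'   year; fewer than 2 rows signals that the stratum cannot be matched.
#' @export
select_controls <- function(candidates, exposure_year,
                            policy = c("nearest_balanced", "random_2")) {
  policy <- match.arg(policy)
  if (nrow(candidates) <= 2L) {
    return(candidates[order(candidates$year), , drop = FALSE])
  }
  if (policy == "random_2") {
    pick <- sample.int(nrow(candidates), 2L)
    return(candidates[sort(pick), , drop = FALSE])
  }
  before <- candidates[candidates$year < exposure_year, , drop = FALSE]
  after <- candidates[candidates$year > exposure_year, , drop = FALSE]
  if (nrow(before) > 0L && nrow(after) > 0L) {
    sel <- rbind(before[which.max(before$year), ],
                 after[which.min(after$year), ])
  } else {
    side <- if (nrow(before) > 0L) before else after
    dist <- abs(side$year - exposure_year)
    sel <- side[order(dist, side$year)[1:2], ]
  }
  sel[order(sel$year), , drop = FALSE]
}

#' Match exposure periods to control windows
#'
#' Builds one matched stratum per exposure period that has at least two
#' eligible control windows; periods with fewer are dropped and recorded
#' in the attrition log. Guards against overlapping exposure periods
#' within a ZIP (corrupt input).
#'
#' @param periods period table from [build_exposure_periods()] (after any
#'   cause filtering).
#' @param exposure_calendar data.frame of all exposed ZIP-days — controls
#'   are checked against every exposed day, not only retained periods.
#' @param window length-2 Date vector, the study window.
#' @param n_lags lag weeks (default 4).
#' @param policy control-selection policy, see [select_controls()].
#' @param check_tail require flood-free lag tails for controls (default
#'   `TRUE`).
#' @param min_controls strata with fewer eligible controls are dropped
#'   (default 2, the design's requirement; 1 relaxes to single-control
#'   strata).
#' @return object of class `matched_strata`: list with `strata` (one row
#'   per stratum: `stratum_id`, `zip`, exposed window, `severity`, `cause`,
#'   control windows and years, `n_lags`) and `attrition` (data.frame:
#'   `stratum_id`, `zip`, `reason`), plus counts `n_periods`, `n_matched`.
#' @export
build_strata <- function(periods, exposure_calendar, window, n_lags = 4L,
                         policy = "nearest_balanced", check_tail = TRUE,
                         min_controls = 2L) {
  stopifnot(is.data.frame(periods))
  # guard: overlapping periods within a ZIP cannot arise from maximal runs
  if (nrow(periods) > 1L) {
    p <- periods[order(periods$zip, as.Date(periods$start_date)), ]
    same_zip <- p$zip[-1L] == p$zip[-nrow(p)]
    overlap <- as.Date(p$start_date[-1L]) <= as.Date(p$end_date[-nrow(p)])
    if (any(same_zip & overlap)) {
      stop("overlapping exposure periods within a ZIP; input is corrupt")
    }
  }
  strata <- list()
  attrition <- list()
  for (i in seq_len(nrow(periods))) {
    per <- periods[i, ]
    sid <- paste0(per$zip, "_", format(as.Date(per$start_date), "%Y%m%d"))
    cand <- candidate_controls(per, exposure_calendar, window, n_lags,
                               check_tail = check_tail)
    exp_year <- as.integer(format(as.Date(per$start_date), "%Y"))
    sel <- select_controls(cand, exp_year, policy)
    if (nrow(sel) < min_controls) {
      attrition[[length(attrition) + 1L]] <- data.frame(
        stratum_id = sid, zip = per$zip,
        reason = if (nrow(cand) == 0L) "no_eligible_control_year"
                 else "insufficient_control_years",
        stringsAsFactors = FALSE)
      next
    }
    strata[[length(strata) + 1L]] <- data.frame(
      stratum_id = sid, zip = per$zip,
      exposed_start = as.Date(per$start_date),
      exposed_end = as.Date(per$end_date),
      duration_days = as.integer(as.Date(per$end_date) -
                                   as.Date(per$start_date)) + 1L,
      severity = if (is.null(per$severity)) NA_character_ else per$severity,
      cause = if (is.null(per$cause)) NA_character_ else per$cause,
      control1_start = sel$start_date[1L], control1_end = sel$end_date[1L],
      control1_year = sel$year[1L],
      control2_start = sel$start_date[2L], control2_end = sel$end_date[2L],
      control2_year = sel$year[2L],
      n_lags = as.integer(n_lags),
      stringsAsFactors = FALSE)
  }
  strata_df <- if (length(strata)) do.call(rbind, strata) else NULL
  attr_df <- if (length(attrition)) do.call(rbind, attrition) else
    data.frame(stratum_id = character(0), zip = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  out <- list(strata = strata_df, attrition = attr_df,
              n_periods = nrow(periods),
              n_matched = if (is.null(strata_df)) 0L else nrow(strata_df))
  class(out) <- "matched_strata"
  out
}

#' @export
print.matched_strata <- function(x, ...) {
  cat("matched_strata:", x$n_matched, "of", x$n_periods,
      "exposure periods matched (2 controls each)\n")
  if (nrow(x$attrition) > 0L) {
    tb <- table(x$attrition$reason)
    for (r in names(tb)) cat("  dropped ", tb[[r]], ": ", r, "\n", sep = "")
  }
  invisible(x)
}
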