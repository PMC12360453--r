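# Descriptive reporting utilities: percentage shares for event censuses
# and cause-of-hospitalisation tables.

#' Percentage share, rounded to printed precision
#'
#' `round(100 * n / total, digits)` — the form in which event-census and
#' cause-distribution shares are reported (e.g. 40 of 72 events -> 56%).
#'
#' @param n numerator count(s).
#' @param total denominator.
#' @param digits decimal places (0 for whole-percent event shares, 1 for
#'   cause-of-hospitalisation shares).
#' @return numeric percentage(s).
#' @export
pct_share <- function(n, total, digits = 0) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * n / total, digits)
}

#' Count and share table for a categorical variable
#'
#' @param x vector of category labels (one per unit), or a named numeric
#'   vector of pre-tabulated counts.
#' @param digits decimal places for the percentage.
#' @return data.frame with `level`, `n`, `pct`, sorted by decreasing `n`.
#' @export
count_shares <- function(x, digits = 0) {
  tb <- if (is.numeric(x) && !is.null(names(x))) x else
    table(x)
  out <- data.frame(level = names(tb), n = as.numeric(tb),
                    pct = pct_share(as.numeric(tb), sum(tb), digits),
                    stringsAsFactors = FALSE)
  out[order(-out$n), , drop = FALSE]
}

#' Event census summary
#'
#' Describes a set of flood events (one row per event): counts and shares
#' by severity and by flood cause, and the duration range.
#'
#' @param events data.frame with one row per event (`event_id`,
#'   `severity`, `cause`, optionally `duration_days`), or a ZIP-day
#'   exposure table from which events are deduplicated by `event_id`.
#' @return list with `n_events`, `severity` (share table), `cause` (share
#'   table), `duration_range` (if available).
#' @export
event_summary <- function(events) {
  if (!is.null(events$event_id) && anyDuplicated(events$event_id)) {
    first <- !duplicated(events$event_id)
    ev <- events[first, , drop = FALSE]
    if (is.null(ev$duration_days)) {
      dur <- tapply(as.Date(events$date), events$event_id,
                    function(d) as.integer(diff(range(d))) + 1L)
      ev$duration_days <- as.integer(dur[ev$event_id])
    }
  } else {
    ev <- events
  }
  out <- list(n_events = nrow(ev),
              severity = count_shares(ev$severity),
              cause = count_shares(ev$cause))
  if (!is.null(ev$duration_days)) {
    out$duration_range <- range(ev$duration_days)
  }
  out
}
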