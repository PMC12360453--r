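# Flood exposure construction: zonal aggregation of flood grids, ZIP-day
# exposure classification, and consecutive-day exposure periods.

SEVERITY_LEVELS <- c("moderate", "high", "extreme")
CAUSE_LEVELS <- c("heavy_rain", "tropical_storm", "other")

#' Zonal flood fraction and area from congruent grids
#'
#' Aggregates a binary flood-extent grid to zones (e.g. ZIP codes) given a
#' zone-id grid of the same shape. For each zone the flooded area is the
#' number of flooded cells times the cell area, and the flooded fraction is
#' the share of the zone's cells that are flooded.
#'
#' @param flood_grid matrix of 0/1 (or logical) flood indicators.
#' @param zone_grid matrix of zone identifiers, same dimensions as
#'   `flood_grid`; cells with `NA` belong to no zone.
#' @param cell_area area of one grid cell in square miles (> 0).
#' @return data.frame with columns `zone`, `frac_flooded`, `area_flooded`.
#' @examples
#' z <- matrix(c(1, 1, 2, 2), 2, 2)
#' f <- matrix(c(1, 0, 0, 0), 2, 2)
#' zonal_flood_fraction(f, z, cell_area = 0.1)
#' @export
zonal_flood_fraction <- function(flood_grid, zone_grid, cell_area) {
  if (!all(dim(flood_grid) == dim(zone_grid))) {
    stop("flood_grid and zone_grid have different shapes: ",
         paste(dim(flood_grid), collapse = "x"), " vs ",
         paste(dim(zone_grid), collapse = "x"))
  }
  if (!is.numeric(cell_area) || length(cell_area) != 1L || cell_area <= 0) {
    stop("cell_area must be a single positive number")
  }
  fl <- as.vector(flood_grid)
  zn <- as.vector(zone_grid)
  if (any(!fl[!is.na(fl)] %in% c(0, 1))) stop("flood_grid must be binary (0/1)")
  keep <- !is.na(zn)
  zn <- zn[keep]
  fl <- fl[keep]
  if (length(zn) == 0L) {
    warning("zone_grid assigns no cells to any zone")
    return(data.frame(zone = character(0), frac_flooded = numeric(0),
                      area_flooded = numeric(0)))
  }
  n_cells <- tapply(fl, zn, length)
  n_flood <- tapply(fl, zn, sum)
  data.frame(
    zone = names(n_cells),
    frac_flooded = as.numeric(n_flood / n_cells),
    area_flooded = as.numeric(n_flood) * cell_area,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Classify a ZIP-day as flood-exposed
#'
#' A ZIP-day is exposed when the flooded fraction of the ZIP's surface area
#' is at least `frac_threshold` (default 0.5%) or the flooded area is at
#' least `area_threshold` square miles (default 5). Both comparisons are
#' inclusive ("at least"). Thresholds are exposed for sensitivity analyses.
#'
#' @param frac_flooded fraction of zone area flooded, in `[0, 1]` (vectorised).
#' @param area_flooded flooded area in square miles, `>= 0` (vectorised).
#' @param frac_threshold fraction threshold (default 0.005).
#' @param area_threshold area threshold in square miles (default 5).
#' @return logical vector: `TRUE` where exposed.
#' @export
classify_exposure <- function(frac_flooded, area_flooded,
                              frac_threshold = 0.005, area_threshold = 5.0) {
  if (any(!is.finite(frac_flooded)) || any(!is.finite(area_flooded))) {
    stop("frac_flooded and area_flooded must be finite")
  }
  if (any(frac_flooded < 0) || any(area_flooded < 0)) {
    stop("frac_flooded and area_flooded must be non-negative")
  }
  frac_flooded >= frac_threshold | area_flooded >= area_threshold
}

#' Build maximal consecutive-day exposure periods
#'
#' Collapses ZIP-day exposure flags into exposure periods: maximal runs of
#' consecutive exposed days within a ZIP. A gap of one or more unexposed
#' days splits periods. Severity of a period is the maximum severity over
#' its days (moderate < high < extreme); the cause set is the union.
#'
#' @param zip_day_flags data.frame with columns `zip`, `date` (Date), and
#'   optionally `event_id`, `severity`, `cause`; one row per exposed
#'   (zip, date). Duplicate (zip, date) rows are an error.
#' @return data.frame of periods: `zip`, `start_date`, `end_date`,
#'   `duration_days`, `severity`, `cause` (comma-joined label set),
#'   `event_ids` (comma-joined).
#' @export
build_exposure_periods <- function(zip_day_flags) {
  stopifnot(is.data.frame(zip_day_flags))
  if (nrow(zip_day_flags) == 0L) {
    return(data.frame(zip = character(0), start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      duration_days = integer(0), severity = character(0),
                      cause = character(0), event_ids = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- as.data.frame(zip_day_flags)
  df$date <- as.Date(df$date)
  if (anyDuplicated(df[, c("zip", "date")])) {
    stop("duplicate (zip, date) rows in exposure flags")
  }
  if (is.null(df$severity)) df$severity <- NA_character_
  if (is.null(df$cause)) df$cause <- NA_character_
  if (is.null(df$event_id)) df$event_id <- NA_character_
  df <- df[order(df$zip, df$date), ]
  # run id increments when zip changes or dates are non-consecutive
  new_run <- c(TRUE, df$zip[-1L] != df$zip[-nrow(df)] |
                 as.integer(diff(df$date)) != 1L)
  run <- cumsum(new_run)
  sev_rank <- function(s) {
    r <- match(s, SEVERITY_LEVELS)
    if (all(is.na(r))) NA_character_ else SEVERITY_LEVELS[max(r, na.rm = TRUE)]
  }
  join_unique <- function(x) {
    x <- unique(x[!is.na(x)])
    if (length(x) == 0L) NA_character_ else paste(sort(x), collapse = ",")
  }
  out <- do.call(rbind, lapply(split(df, run), function(d) {
    data.frame(
      zip = d$zip[1L],
      start_date = min(d$date),
      end_date = max(d$date),
      duration_days = as.integer(max(d$date) - min(d$date)) + 1L,
      severity = sev_rank(d$severity),
      cause = join_unique(d$cause),
      event_ids = join_unique(as.character(d$event_id)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$zip, out$start_date), ]
}

#' Expand exposure periods back to ZIP-day flags
#'
#' Inverse of [build_exposure_periods()]: one row per (zip, date) covered by
#' a period. Used for round-trip checks and to build exposure calendars.
#'
#' @param periods data.frame as returned by [build_exposure_periods()].
#' @return data.frame with columns `zip`, `date`.
#' @export
expand_periods_to_days <- function(periods) {
  if (nrow(periods) == 0L) {
    return(data.frame(zip = character(0), date = as.Date(character(0))))
  }
  days <- lapply(seq_len(nrow(periods)), function(i) {
    data.frame(zip = periods$zip[i],
               date = seq(as.Date(periods$start_date[i]),
                          as.Date(periods$end_date[i]), by = "day"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, days)
  out[order(out$zip, out$date), , drop = FALSE]
}

#' Restrict exposure periods to allowed flood causes
#'
#' Keeps periods whose cause set intersects `allowed` (default: heavy rain
#' and tropical storms, the rain/storm flood restriction). The number of
#' dropped periods is reported via `message()`.
#'
#' @param periods period table from [build_exposure_periods()].
#' @param allowed character vector of allowed cause labels.
#' @return the filtered period table.
#' @export
filter_periods_by_cause <- function(periods,
                                    allowed = c("heavy_rain", "tropical_storm")) {
  if (nrow(periods) == 0L) return(periods)
  keep <- vapply(strsplit(periods$cause, ","), function(cs) {
    any(cs %in% allowed)
  }, logical(1))
  n_drop <- sum(!keep)
  if (n_drop > 0L) {
    message(n_drop, " exposure period(s) dropped by cause filter")
  }
  periods[keep, , drop = FALSE]
}
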