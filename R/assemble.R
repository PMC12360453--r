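# Analytical dataset assembly: expand matched strata into (arm, lag)
# windows, attach outcome counts, person-time offsets and covariate means,
# and build the model design matrix with natural-spline confounder bases.

ARM_LEVELS <- c("exposed", "control_1", "control_2")

#' Lag windows of a matched stratum
#'
#' For each arm (exposed, control_1, control_2): lag 0 is the arm's window
#' itself; lag l (l >= 1) is the 7-day window `[end + 7(l-1) + 1,
#' end + 7l]`.
#'
#' @param stratum one-row data.frame from the `strata` table of
#'   [build_strata()].
#' @param n_lags number of lag weeks; defaults to the stratum's `n_lags`.
#' @return data.frame with `arm`, `lag`, `start_date`, `end_date`.
#' @export
lag_windows <- function(stratum, n_lags = NULL) {
  if (is.null(n_lags)) n_lags <- stratum$n_lags[1]
  arms <- data.frame(
    arm = ARM_LEVELS,
    start = as.Date(c(stratum$exposed_start[1], stratum$control1_start[1],
                      stratum$control2_start[1])),
    end = as.Date(c(stratum$exposed_end[1], stratum$control1_end[1],
                    stratum$control2_end[1])),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(seq_len(nrow(arms)), function(i) {
    e <- arms$end[i]
    lag <- 0:n_lags
    start <- c(arms$start[i], if (n_lags > 0) e + 7L * (1:n_lags - 1L) + 1L)
    end <- c(e, if (n_lags > 0) e + 7L * (1:n_lags))
    data.frame(arm = arms$arm[i], lag = lag, start_date = start,
               end_date = end, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Sum hospitalisation counts in a window
#'
#' Sums the counts for one ZIP, cause and date window, optionally
#' restricted to an admission type. Days with no row in the table count as
#' zero.
#'
#' @param counts data.frame/data.table with `zip`, `date`, `cause`,
#'   `count` and optionally `admission_type`.
#' @param zip,window ZIP id and length-2 Date vector (start, end).
#' @param cause cause label to sum.
#' @param admission_filter `NULL` (all), `"emergency"` or
#'   `"non_emergency"`.
#' @return integer count.
#' @export
aggregate_counts <- function(counts, zip, window, cause,
                             admission_filter = NULL) {
  if (nrow(counts) > 0 && any(counts$count < 0)) {
    stop("negative counts in input")
  }
  if (nrow(counts) == 0L) return(0L)
  sel <- counts$zip == zip & counts$cause == cause &
    as.Date(counts$date) >= as.Date(window[1]) &
    as.Date(counts$date) <= as.Date(window[2])
  if (!is.null(admission_filter)) {
    sel <- sel & counts$admission_type == admission_filter
  }
  as.integer(sum(counts$count[sel]))
}

#' Person-time offset for a window
#'
#' Person-days contributed by one ZIP over a date window: the sum over
#' calendar days of that day's ZIP-year enrollee count (denominators are
#' held at ZIP-year resolution).
#'
#' @param population data.frame with `zip`, `year`, `enrollees`.
#' @param zip,window ZIP id and (start, end) Dates.
#' @return person-days (positive real); errors on a missing or
#'   non-positive ZIP-year denominator.
#' @export
person_time_offset <- function(population, zip, window) {
  days <- seq(as.Date(window[1]), as.Date(window[2]), by = "day")
  yrs <- as.integer(format(days, "%Y"))
  need <- unique(yrs)
  pop <- population[population$zip == zip & population$year %in% need, ]
  missing_yr <- setdiff(need, pop$year)
  if (length(missing_yr)) {
    stop("missing population for zip ", zip, ", year(s) ",
         paste(missing_yr, collapse = ", "))
  }
  enr <- pop$enrollees[match(yrs, pop$year)]
  if (any(enr <= 0)) {
    stop("non-positive enrollee count for zip ", zip)
  }
  sum(as.numeric(enr))
}

#' Window means of daily covariates
#'
#' Arithmetic mean of each covariate over the window's days for one ZIP.
#' Missing days are tolerated up to `tolerance` (fraction of the window,
#' default 0: any missing day is an error).
#'
#' @param covariates data.frame/data.table with `zip`, `date` and
#'   covariate columns.
#' @param zip,window ZIP id and (start, end) Dates.
#' @param vars covariate columns to average.
#' @param tolerance maximum tolerated fraction of missing days.
#' @return named numeric vector of means.
#' @export
aggregate_covariates <- function(covariates, zip, window,
                                 vars = COVARIATE_NAMES, tolerance = 0) {
  days <- seq(as.Date(window[1]), as.Date(window[2]), by = "day")
  sub <- covariates[covariates$zip == zip &
                      as.Date(covariates$date) %in% days, , drop = FALSE]
  n_missing <- length(days) - nrow(sub)
  if (n_missing / length(days) > tolerance) {
    stop("covariates missing for ", n_missing, " of ", length(days),
         " day(s) in window (zip ", zip, ")")
  }
  vapply(vars, function(v) mean(sub[[v]]), numeric(1))
}

#' Natural cubic spline basis with stored knots
#'
#' Thin wrapper over [splines::ns()]: boundary knots at `min(x)` and
#' `max(x)`, `df - 1` interior knots at equally spaced quantiles (so
#' `df = 2` places a single interior knot at the median). The returned
#' object stores the knots so new data are evaluated on the same basis;
#' beyond the boundary knots the basis extrapolates linearly (second
#' derivative zero), the defining property of a natural spline.
#'
#' @param x numeric vector with at least `df + 1` distinct values.
#' @param df degrees of freedom (default 2).
#' @return object of class `spline_basis`: list with `df`,
#'   `interior_knots`, `boundary_knots`, `basis` (matrix, `length(x)` by
#'   `df`).
#' @export
natural_spline_basis <- function(x, df = 2L) {
  if (length(unique(x)) < df + 1L) {
    stop("need at least df + 1 = ", df + 1L,
         " distinct values for a df=", df, " natural spline")
  }
  b <- splines::ns(x, df = df)
  out <- list(df = df,
              interior_knots = as.numeric(attr(b, "knots")),
              boundary_knots = as.numeric(attr(b, "Boundary.knots")),
              basis = unclass(b)[, , drop = FALSE])
  attributes(out$basis) <- list(dim = dim(b))
  class(out) <- "spline_basis"
  out
}

#' @export
predict.spline_basis <- function(object, newx, ...) {
  b <- splines::ns(newx, knots = object$interior_knots,
                   Boundary.knots = object$boundary_knots)
  m <- unclass(b)[, , drop = FALSE]
  attributes(m) <- list(dim = dim(b))
  m
}

# decimal year at the midpoint of a window
decimal_year <- function(start, end) {
  mid <- as.Date(start) + floor(as.numeric(as.Date(end) - as.Date(start)) / 2)
  yr <- as.integer(format(mid, "%Y"))
  day0 <- as.Date(sprintf("%04d-01-01", yr))
  ndays <- as.numeric(as.Date(sprintf("%04d-01-01", yr + 1L)) - day0)
  yr + (as.numeric(mid - day0) + 0.5) / ndays
}

#' Assemble the distributed-lag analytical dataset
#'
#' Expands every matched stratum into its `3 * (n_lags + 1)` (arm, lag)
#' windows and attaches, per window: the outcome count for `cause`, the
#' person-day offset, the decimal year at the window midpoint, and the
#' window means of the daily covariates. Builds the model design matrix:
#' `n_lags + 1` exposure-by-lag indicators (1 iff arm = exposed and
#' lag = l), a natural-spline basis (df 2) for year, and one df-2 spline
#' per covariate mean. Spline bases are fit on the full dataset, matching
#' a single model fit per cause.
#'
#' @param strata a `matched_strata` object or its `strata` data.frame.
#' @param counts,covariates,population tables as produced by
#'   [simulate_flood_study()] (or equivalently structured real data).
#' @param cause cause label to analyse.
#' @param admission_filter optional admission type restriction.
#' @param cov_names covariates to adjust for (default all six); `NULL` or
#'   empty for no covariate splines.
#' @param spline_df spline degrees of freedom (default 2).
#' @param cov_tolerance missing-day tolerance for covariate means.
#' @return object of class `analytical_dataset`: list with `rows`
#'   (data.frame of analytical rows), `X` (design matrix), `y`, `offset`
#'   (log person-days), `stratum` (factor), `lag_cols` (names of the
#'   exposure-by-lag columns), `splines` (fitted bases), `cause`,
#'   `n_lags`.
#' @export
build_analytical_dataset <- function(strata, counts, covariates, population,
                                     cause, admission_filter = NULL,
                                     cov_names = COVARIATE_NAMES,
                                     spline_df = 2L, cov_tolerance = 0) {
  if (inherits(strata, "matched_strata")) strata <- strata$strata
  if (is.null(strata) || nrow(strata) == 0L) stop("no matched strata")
  n_lags <- strata$n_lags[1]

  win <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    lw <- lag_windows(strata[i, ])
    lw$stratum_id <- strata$stratum_id[i]
    lw$zip <- strata$zip[i]
    lw
  }))
  win <- data.table::as.data.table(win)

  # day-level expansion once, then grouped joins (fast and exact)
  days <- win[, .(date = seq(start_date, end_date, by = "day")),
              by = .(stratum_id, zip, arm, lag)]
  days[, year := data.table::year(date)]

  ct <- data.table::as.data.table(counts)
  if (nrow(ct) > 0 && any(ct$count < 0)) stop("negative counts in input")
  ct <- ct[ct$cause == cause]
  if (!is.null(admission_filter)) {
    ct <- ct[ct$admission_type == admission_filter]
  }
  ct <- ct[, .(count = sum(count)), by = .(zip, date)]
  days <- ct[days, on = c("zip", "date")]
  days[is.na(count), count := 0L]

  pop <- data.table::as.data.table(population)
  days <- pop[days, on = c("zip", "year")]
  if (anyNA(days$enrollees)) {
    bad <- unique(days[is.na(enrollees), .(zip, year)])
    stop("missing population for ", paste(bad$zip, bad$year, sep = "/",
                                          collapse = ", "))
  }
  if (any(days$enrollees <= 0)) stop("non-positive enrollee count")

  cv <- data.table::as.data.table(covariates)
  use_cov <- length(cov_names) > 0
  if (use_cov) {
    missing_cov <- setdiff(cov_names, names(cv))
    if (length(missing_cov)) {
      stop("covariate table lacks column(s): ",
           paste(missing_cov, collapse = ", "))
    }
    days <- cv[, c("zip", "date", cov_names), with = FALSE][
      days, on = c("zip", "date")]
    n_miss <- days[, .(miss = sum(is.na(.SD[[1]])), n = .N),
                   .SDcols = cov_names[1],
                   by = .(stratum_id, arm, lag)]
    if (any(n_miss$miss / n_miss$n > cov_tolerance)) {
      stop("covariate coverage below tolerance in ",
           sum(n_miss$miss / n_miss$n > cov_tolerance), " window(s)")
    }
  }

  agg <- days[, c(list(count = sum(count),
                       person_days = sum(as.numeric(enrollees)),
                       start_date = min(date), end_date = max(date)),
                  if (use_cov) lapply(.SD, mean, na.rm = TRUE)),
              .SDcols = if (use_cov) cov_names else character(0),
              by = .(stratum_id, zip, arm, lag)]
  agg[, year_frac := decimal_year(start_date, end_date)]
  data.table::setorder(agg, stratum_id, arm, lag)
  rows <- as.data.frame(agg)
  rows$cause <- cause

  # design matrix: exposure-by-lag indicators, then spline terms
  lag_cols <- paste0("exp_lag", 0:n_lags)
  X_lag <- sapply(0:n_lags, function(l) {
    as.numeric(rows$arm == "exposed" & rows$lag == l)
  })
  colnames(X_lag) <- lag_cols

  spl <- list()
  spl$year <- natural_spline_basis(rows$year_frac, df = spline_df)
  X_spl <- spl$year$basis
  colnames(X_spl) <- paste0("year_ns", seq_len(spline_df))
  if (use_cov) {
    for (v in cov_names) {
      spl[[v]] <- natural_spline_basis(rows[[v]], df = spline_df)
      m <- spl[[v]]$basis
      colnames(m) <- paste0(v, "_ns", seq_len(spline_df))
      X_spl <- cbind(X_spl, m)
    }
  }
  X <- cbind(X_lag, X_spl)
  rownames(X) <- NULL

  out <- list(rows = rows, X = X, y = rows$count,
              offset = log(rows$person_days),
              stratum = factor(rows$stratum_id),
              lag_cols = lag_cols, splines = spl, cause = cause,
              n_lags = n_lags)
  class(out) <- "analytical_dataset"
  out
}

#' @export
print.analytical_dataset <- function(x, ...) {
  cat("analytical_dataset: cause '", x$cause, "', ",
      nlevels(x$stratum), " strata x 3 arms x ", x$n_lags + 1,
      " lags = ", nrow(x$rows), " rows, ", ncol(x$X),
      " design columns\n", sep = "")
  invisible(x)
}
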