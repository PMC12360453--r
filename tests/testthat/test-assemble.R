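# Dataset assembly: lag-window arithmetic, count/offset/covariate
# aggregation, natural-spline bases, and the analytical design matrix.

test_that("lag windows follow the end + 7(l-1) + 1 .. end + 7l rule", {
  s <- make_stratum_row(exposed_start = "2005-06-01",
                        exposed_end = "2005-06-03",
                        c1_start = "2003-06-01", c2_start = "2007-06-01")
  lw <- lag_windows(s)
  expect_equal(nrow(lw), 3 * 5)
  e <- lw[lw$arm == "exposed", ]
  expect_equal(e$start_date[e$lag == 0], as.Date("2005-06-01"))
  expect_equal(e$end_date[e$lag == 0], as.Date("2005-06-03"))
  expect_equal(e$start_date[e$lag == 1], as.Date("2005-06-04"))
  expect_equal(e$end_date[e$lag == 1], as.Date("2005-06-10"))
  expect_equal(e$start_date[e$lag == 4], as.Date("2005-06-25"))
  expect_equal(e$end_date[e$lag == 4], as.Date("2005-07-01"))
  expect_true(all(lw$end_date[lw$lag > 0] - lw$start_date[lw$lag > 0] == 6))

  # extended 12-week secondary analysis: 13 windows per arm
  s12 <- make_stratum_row(exposed_start = "2005-06-01",
                          exposed_end = "2005-06-03",
                          c1_start = "2003-06-01", c2_start = "2007-06-01",
                          n_lags = 12)
  expect_equal(nrow(lag_windows(s12)), 3 * 13)

  # duration-1 period: lag-0 window of one day
  s1 <- make_stratum_row(exposed_start = "2005-06-01",
                         exposed_end = "2005-06-01",
                         c1_start = "2003-06-01", c2_start = "2007-06-01")
  l0 <- lag_windows(s1)
  expect_true(all(l0$start_date[l0$lag == 0] == l0$end_date[l0$lag == 0]))
})

test_that("window count aggregation sums the covered days", {
  d0 <- as.Date("2005-06-01")
  counts <- data.frame(zip = "Z1", date = d0 + 0:2, cause = "all",
                       admission_type = c("emergency", "emergency",
                                          "non_emergency"),
                       count = c(2L, 0L, 5L))
  expect_equal(aggregate_counts(counts, "Z1", c(d0, d0 + 2), "all"), 7L)
  expect_equal(aggregate_counts(counts[0, ], "Z1", c(d0, d0 + 2), "all"), 0L)
  expect_equal(aggregate_counts(counts, "Z1", c(d0, d0 + 2), "all",
                                admission_filter = "emergency"), 2L)
  expect_equal(aggregate_counts(counts, "Z2", c(d0, d0 + 2), "all"), 0L)
  counts$count[1] <- -1L
  expect_error(aggregate_counts(counts, "Z1", c(d0, d0 + 2), "all"),
               "negative")
})

test_that("person-time offsets sum day-wise ZIP-year enrollee counts", {
  pop <- data.frame(zip = "Z1", year = c(2004, 2005),
                    enrollees = c(1000L, 1200L))
  expect_equal(person_time_offset(pop, "Z1",
                                  c(as.Date("2004-03-01"),
                                    as.Date("2004-03-07"))), 7000)
  # straddling Dec 31: 2 days at 1000 + 5 days at 1200
  expect_equal(person_time_offset(pop, "Z1",
                                  c(as.Date("2004-12-30"),
                                    as.Date("2005-01-05"))), 8000)
  expect_error(person_time_offset(pop, "Z1",
                                  c(as.Date("2006-01-01"),
                                    as.Date("2006-01-02"))), "2006")
  pop0 <- transform(pop, enrollees = c(0L, 1200L))
  expect_error(person_time_offset(pop0, "Z1",
                                  c(as.Date("2004-03-01"),
                                    as.Date("2004-03-02"))), "non-positive")
})

test_that("covariate window means are arithmetic means with strict coverage", {
  d0 <- as.Date("2005-06-01")
  cov <- data.frame(zip = "Z1", date = d0 + 0:6, tmax = 1:7, rhmax = 5,
                    wind = 2, pm25 = 8, no2 = 10, o3 = 30)
  m <- aggregate_covariates(cov, "Z1", c(d0, d0 + 6))
  expect_equal(unname(m["tmax"]), 4.0)
  expect_equal(unname(m["rhmax"]), 5.0)
  expect_error(aggregate_covariates(cov[-3, ], "Z1", c(d0, d0 + 6)),
               "missing")
  # tolerated missingness
  m2 <- aggregate_covariates(cov[-3, ], "Z1", c(d0, d0 + 6),
                             tolerance = 0.2)
  expect_equal(unname(m2["tmax"]), mean((1:7)[-3]))
})

test_that("df-2 natural splines put one interior knot at the median", {
  b <- natural_spline_basis(1:100, df = 2)
  expect_equal(b$interior_knots, 50.5)
  expect_equal(b$boundary_knots, c(1, 100))
  expect_equal(qr(b$basis)$rank, 2)
  # natural = linear beyond the boundary knots: zero second differences
  grid <- seq(150, 200, by = 1)
  pb <- predict(b, grid)
  for (j in 1:2) {
    expect_lt(max(abs(diff(diff(pb[, j])))), 1e-9)
  }
  # evaluation at the training points reproduces the basis
  expect_equal(predict(b, 1:100), b$basis, tolerance = 1e-12)
  expect_error(natural_spline_basis(c(1, 1, 2), df = 2), "distinct")
})

test_that("the analytical dataset has 3(n_lags+1) rows per stratum", {
  set.seed(33)
  strata <- do.call(rbind, lapply(1:10, function(i) {
    start <- as.Date("2006-05-01") + (i - 1) * 40
    make_stratum_row(zip = sprintf("Z%04d", i), exposed_start = start,
                     exposed_end = start + 2,
                     c1_start = format(start - 730),
                     c2_start = format(start + 730))
  }))
  ms <- as_matched_strata(strata)
  dates <- seq(as.Date("2004-01-01"), as.Date("2009-12-31"), by = "day")
  zips <- sprintf("Z%04d", 1:10)
  cov <- do.call(rbind, lapply(zips, function(z) {
    data.frame(zip = z, date = dates,
               tmax = 15 + 10 * sin(2 * pi * as.integer(format(dates, "%j")) / 365) +
                 rnorm(length(dates)),
               rhmax = 70 + rnorm(length(dates)), wind = 4 + rnorm(length(dates), 0, 0.5),
               pm25 = 9 + rnorm(length(dates)), no2 = 12 + rnorm(length(dates)),
               o3 = 38 + rnorm(length(dates)))
  }))
  pop <- expand.grid(zip = zips, year = 2004:2009,
                     stringsAsFactors = FALSE)
  pop$enrollees <- 1000L
  counts <- data.frame(zip = sample(zips, 400, TRUE),
                       date = sample(dates, 400, TRUE), cause = "all",
                       admission_type = "emergency", count = 1L)
  counts <- aggregate(count ~ zip + date + cause + admission_type,
                      counts, sum)
  ds <- build_analytical_dataset(ms, counts, cov, pop, "all")
  expect_equal(nrow(ds$rows), 10 * 3 * 5)
  expect_equal(ncol(ds$X), 5 + 2 * 7)  # lags + year + 6 covariate splines
  # exposure-by-lag indicators: sum 5 on exposed rows, 0 on controls
  ind_sum <- rowSums(ds$X[, ds$lag_cols])
  expect_true(all(ind_sum[ds$rows$arm == "exposed"] %in% c(0, 1)))
  agg <- tapply(rowSums(ds$X[, ds$lag_cols]),
                list(ds$rows$stratum_id, ds$rows$arm), sum)
  expect_true(all(agg[, "exposed"] == 5))
  expect_true(all(agg[, c("control_1", "control_2")] == 0))
  expect_true(all(is.finite(ds$offset)))
  expect_true(all(ds$rows$person_days > 0))
})

test_that("assembled rows match a hand-built two-stratum expectation", {
  s1 <- make_stratum_row(zip = "A", exposed_start = "2005-06-01",
                         exposed_end = "2005-06-03",
                         c1_start = "2004-06-01", c2_start = "2006-06-01",
                         n_lags = 1)
  s2 <- make_stratum_row(zip = "B", exposed_start = "2005-07-10",
                         exposed_end = "2005-07-10",
                         c1_start = "2004-07-10", c2_start = "2006-07-10",
                         n_lags = 1)
  ms <- as_matched_strata(rbind(s1, s2))
  dates <- seq(as.Date("2004-01-01"), as.Date("2006-12-31"), by = "day")
  pop <- expand.grid(zip = c("A", "B"), year = 2004:2006,
                     stringsAsFactors = FALSE)
  pop$enrollees <- c(100L, 200L)[match(pop$zip, c("A", "B"))]
  counts <- data.frame(
    zip = c("A", "A", "A", "B"),
    date = as.Date(c("2005-06-02", "2005-06-07", "2004-06-01",
                     "2005-07-12")),
    cause = "all", admission_type = "emergency", count = c(3L, 2L, 1L, 4L))
  ds <- build_analytical_dataset(ms, counts, NULL, pop, "all",
                                 cov_names = NULL)
  expect_equal(nrow(ds$rows), 2 * 3 * 2)
  r <- ds$rows
  g <- function(zip, arm, lag) r[r$zip == zip & r$arm == arm & r$lag == lag, ]
  expect_equal(g("A", "exposed", 0)$count, 3L)       # Jun 1-3
  expect_equal(g("A", "exposed", 0)$person_days, 300)
  expect_equal(g("A", "exposed", 1)$count, 2L)       # Jun 4-10
  expect_equal(g("A", "exposed", 1)$person_days, 700)
  expect_equal(g("A", "control_1", 0)$count, 1L)     # 2004-06-01..03
  expect_equal(g("B", "exposed", 1)$count, 4L)       # Jul 11-17
  expect_equal(g("B", "exposed", 1)$person_days, 1400)
  expect_equal(g("B", "control_2", 0)$count, 0L)
  # decimal year at the window midpoint
  expect_equal(g("A", "exposed", 0)$year_frac,
               2005 + (as.numeric(as.Date("2005-06-02") -
                                    as.Date("2005-01-01")) + 0.5) / 365)
})
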