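# Conditional quasi-Poisson distributed-lag model, fit by profiled IRLS:
# stratum intercepts are profiled out in closed form each iteration (for
# Poisson data this reproduces the conditional-likelihood point estimates
# exactly), a Newton step updates the remaining coefficients on the
# within-stratum weighted-centred design, and a Pearson dispersion scales
# the covariance.

#' Closed-form profiled stratum intercepts
#'
#' Given coefficients `beta` for the shared design, the Poisson
#' log-likelihood is maximised in each stratum intercept at
#' `alpha_s = log(sum_s y) - log(sum_s exp(x'beta + log offset))`.
#' Strata with zero total count have no finite maximiser and are dropped
#' with a warning (they contribute nothing to the conditional likelihood).
#'
#' @param beta coefficient vector (length `ncol(dataset$X)`).
#' @param dataset an `analytical_dataset` (or a compatible list with `X`,
#'   `y`, `offset`, `stratum`).
#' @return named numeric vector of intercepts for strata with positive
#'   total count.
#' @export
profile_stratum_intercepts <- function(beta, dataset) {
  eta <- drop(dataset$X %*% beta) + dataset$offset
  tot_y <- tapply(dataset$y, dataset$stratum, sum)
  tot_e <- tapply(exp(eta), dataset$stratum, sum)
  zero <- tot_y == 0
  if (any(zero)) {
    warning(sum(zero), " stratum/strata with zero total count dropped")
  }
  log(tot_y[!zero]) - log(tot_e[!zero])
}

# drop zero-count strata; returns reduced components
drop_empty_strata <- function(X, y, off, stratum, quiet = FALSE) {
  stratum <- droplevels(as.factor(stratum))
  tot <- tapply(y, stratum, sum)
  empty <- names(tot)[tot == 0]
  if (length(empty)) {
    if (!quiet) {
      warning(length(empty),
              " stratum/strata with zero total count dropped from fit")
    }
    keep <- !(as.character(stratum) %in% empty)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
    off <- off[keep]
    stratum <- droplevels(stratum[keep])
  }
  list(X = X, y = y, off = off, stratum = stratum,
       n_dropped = length(empty))
}

# within-stratum weighted centring of the columns of X
center_within <- function(X, w, stratum) {
  idx <- as.integer(stratum)
  sw <- rowsum(w, idx)
  means <- rowsum(X * w, idx) / as.numeric(sw)
  X - means[idx, , drop = FALSE]
}

#' Fit the conditional quasi-Poisson distributed-lag model
#'
#' Maximises the Poisson likelihood with one intercept per matched stratum
#' by Newton iteration on the shared coefficients, with the stratum
#' intercepts profiled out in closed form at every step — numerically
#' identical to conditional (fixed-effects) Poisson estimation. The
#' covariance of the shared coefficients is the dispersion-scaled inverse
#' of the profile Fisher information (the Schur complement of the full
#' information with respect to the intercepts), and the dispersion is the
#' Pearson chi-square divided by `n - p - S` (observations minus shared
#' parameters minus retained strata), the standard quasi-Poisson
#' estimator.
#'
#' @param dataset an `analytical_dataset` (or compatible list).
#' @param tol convergence tolerance on the max absolute coefficient change
#'   (default 1e-10).
#' @param max_iter maximum Newton iterations (default 100).
#' @param dispersion_floor optional lower bound for the dispersion (e.g. 1
#'   to forbid deflation); default `NULL`, no floor.
#' @return object of class `cqp_fit`: `beta`, `vcov`, `dispersion`,
#'   `n_obs`, `n_params`, `n_strata`, `converged`, `n_iter`, `deviance`,
#'   `pearson_chi2`, `alpha` (stratum intercepts), `lag_cols`, `cause`,
#'   `n_lags`.
#' @export
fit_conditional_quasipoisson <- function(dataset, tol = 1e-10,
                                         max_iter = 100L,
                                         dispersion_floor = NULL) {
  d <- drop_empty_strata(dataset$X, dataset$y, dataset$offset,
                         dataset$stratum)
  X <- d$X; y <- d$y; off <- d$off; stratum <- d$stratum
  n <- length(y); p <- ncol(X); S <- nlevels(stratum)

  # rank check on the centred design (stratum dummies absorb means)
  Xc0 <- center_within(X, rep(1, n), stratum)
  qr0 <- qr(Xc0)
  if (qr0$rank < p) {
    bad <- colnames(X)[qr0$pivot[(qr0$rank + 1):p]]
    stop("design matrix rank deficient after conditioning on strata; ",
         "collinear column(s): ", paste(bad, collapse = ", "))
  }

  beta <- rep(0, p)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- drop(X %*% beta) + off
    # profiled intercepts in closed form
    tot_y <- rowsum(y, stratum)
    tot_e <- rowsum(exp(eta), stratum)
    alpha <- log(as.numeric(tot_y)) - log(as.numeric(tot_e))
    mu <- exp(eta + alpha[as.integer(stratum)])
    Xc <- center_within(X, mu, stratum)
    # profile score and information: X'(y - mu), Xc' diag(mu) Xc
    g <- drop(crossprod(X, y - mu))
    H <- crossprod(Xc * mu, Xc)
    step <- tryCatch(solve(H, g), error = function(e) {
      stop("singular profile information at iteration ", iter, ": ",
           conditionMessage(e))
    })
    beta <- beta + step
    if (max(abs(step)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }

  eta <- drop(X %*% beta) + off
  tot_y <- rowsum(y, stratum)
  tot_e <- rowsum(exp(eta), stratum)
  alpha <- log(as.numeric(tot_y)) - log(as.numeric(tot_e))
  names(alpha) <- levels(stratum)
  mu <- exp(eta + alpha[as.integer(stratum)])
  pearson <- sum((y - mu)^2 / mu)
  dof <- n - p - S
  if (dof <= 0) stop("non-positive residual degrees of freedom (n - p - S)")
  phi <- pearson / dof
  if (!is.null(dispersion_floor)) phi <- max(phi, dispersion_floor)
  Xc <- center_within(X, mu, stratum)
  info <- crossprod(Xc * mu, Xc)
  V <- phi * solve(info)
  V <- (V + t(V)) / 2
  dimnames(V) <- list(colnames(X), colnames(X))
  dev_terms <- ifelse(y > 0, y * log(y / mu), 0) - (y - mu)
  names(beta) <- colnames(X)

  out <- list(beta = beta, vcov = V, dispersion = phi, n_obs = n,
              n_params = p, n_strata = S, converged = converged,
              n_iter = iter, deviance = 2 * sum(dev_terms),
              pearson_chi2 = pearson, alpha = alpha,
              n_strata_dropped = d$n_dropped,
              lag_cols = dataset$lag_cols,
              cause = dataset$cause, n_lags = dataset$n_lags,
              fitted = mu)
  class(out) <- "cqp_fit"
  out
}

#' @export
print.cqp_fit <- function(x, ...) {
  cat("Conditional quasi-Poisson fit",
      if (!is.null(x$cause)) paste0("(cause: ", x$cause, ")"), "\n")
  cat("  ", x$n_obs, "rows,", x$n_strata, "strata,", x$n_params,
      "coefficients;", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  cat("  dispersion:", format(x$dispersion, digits = 4),
      " deviance:", format(x$deviance, digits = 6), "\n")
  if (!is.null(x$lag_cols)) {
    b <- x$beta[x$lag_cols]
    se <- sqrt(diag(x$vcov)[x$lag_cols])
    cat("  lag terms (log RR +/- SE):\n")
    for (i in seq_along(b)) {
      cat(sprintf("    %-10s %8.4f  (%.4f)\n", names(b)[i], b[i], se[i]))
    }
  }
  invisible(x)
}

# Bonferroni-adjusted normal quantile
bonferroni_z <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  stats::qnorm(1 - alpha / (2 * m))
}

effect_row <- function(est, se, z, cause, lag, alpha, m) {
  data.frame(cause = cause, lag = lag,
             pct_change = (exp(est) - 1) * 100,
             ci_low = (exp(est - z * se) - 1) * 100,
             ci_high = (exp(est + z * se) - 1) * 100,
             log_rr = est, se = se, alpha = alpha, m = m,
             stringsAsFactors = FALSE)
}

#' Per-lag relative percentage changes with corrected CIs
#'
#' Transforms each exposure-by-lag coefficient to a relative percentage
#' change, `(RR - 1) * 100` with `RR = exp(beta_l)`, and builds
#' Bonferroni-corrected confidence intervals using the normal quantile
#' `1 - alpha / (2m)` for `m` simultaneous comparisons.
#'
#' @param fit a `cqp_fit`.
#' @param alpha nominal error rate before correction (default 0.05).
#' @param m number of simultaneous comparisons; default: the number of lag
#'   estimates in the model (`n_lags + 1`).
#' @return data.frame with `cause`, `lag`, `pct_change`, `ci_low`,
#'   `ci_high`, `log_rr`, `se`, `alpha`, `m`.
#' @export
lag_effects <- function(fit, alpha = 0.05, m = NULL) {
  if (!fit$converged) warning("model fit did not converge")
  cols <- fit$lag_cols
  if (is.null(m)) m <- length(cols)
  z <- bonferroni_z(alpha, m)
  est <- fit$beta[cols]
  se <- sqrt(diag(fit$vcov)[cols])
  out <- do.call(rbind, lapply(seq_along(cols), function(i) {
    effect_row(est[i], se[i], z, fit$cause, i - 1L, alpha, m)
  }))
  rownames(out) <- NULL
  out
}

#' Mean effect across the exposure period and lag weeks
#'
#' Uniform-weight linear combination of the selected lag coefficients on
#' the log scale: the point estimate is `(exp(mean(beta_lags)) - 1) * 100`
#' with variance `c' V c`, `c` the uniform weight vector. An arithmetic
#' mean of the per-lag percentage changes is available via
#' `scale = "pct"`.
#'
#' @param fit a `cqp_fit`.
#' @param lags integer lags to average (default all, `0:n_lags`).
#' @param alpha,m as in [lag_effects()].
#' @param scale `"log"` (default; delta method on the averaged log RR) or
#'   `"pct"` (arithmetic mean of percentage changes, CI by delta method).
#' @return one-row data.frame like [lag_effects()], with `lag = "mean"`.
#' @export
mean_effect <- function(fit, lags = NULL, alpha = 0.05, m = NULL,
                        scale = c("log", "pct")) {
  scale <- match.arg(scale)
  if (!fit$converged) warning("model fit did not converge")
  if (is.null(lags)) lags <- 0:fit$n_lags
  if (length(lags) == 0L) stop("empty lag set")
  cols <- fit$lag_cols[lags + 1L]
  if (anyNA(cols)) stop("requested lag outside the fitted range")
  if (is.null(m)) m <- length(fit$lag_cols)
  z <- bonferroni_z(alpha, m)
  V <- fit$vcov[cols, cols, drop = FALSE]
  if (scale == "log") {
    cw <- rep(1 / length(cols), length(cols))
    est <- sum(cw * fit$beta[cols])
    se <- sqrt(drop(t(cw) %*% V %*% cw))
    out <- effect_row(est, se, z, fit$cause, NA_integer_, alpha, m)
  } else {
    # mean of (exp(b_l) - 1) * 100; gradient 100 * exp(b_l) / L
    b <- fit$beta[cols]
    grad <- 100 * exp(b) / length(b)
    pct <- mean((exp(b) - 1) * 100)
    se_pct <- sqrt(drop(t(grad) %*% V %*% grad))
    out <- data.frame(cause = fit$cause, lag = NA_integer_,
                      pct_change = pct, ci_low = pct - z * se_pct,
                      ci_high = pct + z * se_pct, log_rr = NA_real_,
                      se = se_pct, alpha = alpha, m = m,
                      stringsAsFactors = FALSE)
  }
  out$lag_label <- "mean"
  out
}

#' Dummy-variable Poisson maximum likelihood (test oracle)
#'
#' Maximises the full Poisson log-likelihood with explicit stratum
#' indicator columns using a generic quasi-Newton optimiser
#' ([stats::optim()], BFGS, analytic gradient). Intended as an independent
#' cross-check of [fit_conditional_quasipoisson()] on small datasets; the
#' two must agree because profiling the intercepts and estimating them
#' jointly maximise the same likelihood.
#'
#' @param dataset an `analytical_dataset` (small; the dummy design grows
#'   with the number of strata).
#' @param reltol optimiser relative tolerance.
#' @return named vector: the shared coefficients (stratum intercepts
#'   discarded).
#' @export
oracle_fit_dummy_poisson <- function(dataset, reltol = 1e-14) {
  d <- drop_empty_strata(dataset$X, dataset$y, dataset$offset,
                         dataset$stratum, quiet = TRUE)
  X <- d$X; y <- d$y; off <- d$off; stratum <- d$stratum
  D <- matrix(0, length(y), nlevels(stratum))
  D[cbind(seq_along(y), as.integer(stratum))] <- 1
  Z <- cbind(D, X)
  if (qr(Z)$rank < ncol(Z)) {
    stop("dummy design rank deficient; coefficients inestimable")
  }
  negll <- function(th) {
    eta <- drop(Z %*% th) + off
    -sum(y * eta - exp(eta))
  }
  grad <- function(th) {
    eta <- drop(Z %*% th) + off
    -drop(crossprod(Z, y - exp(eta)))
  }
  th0 <- rep(0, ncol(Z))
  opt <- stats::optim(th0, negll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = reltol))
  # polish with a second start from the optimum (BFGS can stop early)
  opt <- stats::optim(opt$par, negll, grad, method = "BFGS",
                      control = list(maxit = 2000, reltol = reltol))
  beta <- opt$par[(ncol(D) + 1):ncol(Z)]
  names(beta) <- colnames(X)
  beta
}
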