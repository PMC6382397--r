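#' Basic bootstrap confidence interval
#'
#' The basic (reflected) bootstrap of Davison & Hinkley: with bootstrap
#' quantiles `q_lo`, `q_hi` of the resampled statistic, the interval is
#' `(2 * est - q_hi, 2 * est - q_lo)`. Deterministic under a fixed RNG
#' state.
#'
#' @param x Numeric sample (>= 2 values).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param n_boot Number of resamples (default 1000; a warning below 100).
#' @param conf Confidence level (default 0.95).
#' @return List `estimate`, `lower`, `upper`, `n_boot`, `conf`.
#' @export
bootstrap_ci <- function(x, statistic = mean, n_boot = 1000, conf = 0.95) {
  if (length(x) < 2) stop("need at least 2 values")
  if (n_boot < 100) warning("n_boot < 100: unstable interval")
  est <- statistic(x)
  n <- length(x)
  boots <- vapply(seq_len(n_boot), function(i) {
    statistic(x[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
  list(estimate = est, lower = 2 * est - q[2], upper = 2 * est - q[1],
       n_boot = n_boot, conf = conf)
}

#' Kaplan-Meier survival fit with censoring-aware median CI
#'
#' Product-limit estimation via the survival package, with log-log
#' transformed Greenwood confidence bands. The median is the first event
#' time at which the survival curve drops to 0.5 or below; its confidence
#' interval is obtained Brookmeyer-Crowley style by intersecting the
#' confidence band with 0.5.
#'
#' @param time Observed times (event or censoring), > 0.
#' @param censored Logical: `TRUE` for right-censored observations.
#' @param conf Confidence level for the bands.
#' @return List of class `km_fit`: `time`, `surv`, `lower`, `upper`,
#'   `n_events`, `median`, `median_ci`, `all_censored`.
#' @export
km_fit <- function(time, censored = rep(FALSE, length(time)), conf = 0.95) {
  stopifnot(length(time) == length(censored))
  event <- !censored
  if (!any(event)) {
    return(structure(list(
      time = sort(time), surv = rep(1, length(time)),
      lower = rep(NA_real_, length(time)), upper = rep(NA_real_, length(time)),
      n_events = 0L, median = NA_real_,
      median_ci = c(lower = NA_real_, upper = NA_real_), all_censored = TRUE
    ), class = "km_fit"))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "log-log", conf.int = conf)
  first_below <- function(s) {
    i <- which(!is.na(s) & s <= 0.5)
    if (length(i)) fit$time[i[1]] else NA_real_
  }
  structure(list(
    time = fit$time, surv = fit$surv,
    lower = fit$lower, upper = fit$upper,
    n_events = sum(event),
    median = first_below(fit$surv),
    # median CI: times where the band still contains 0.5 — from the first
    # time the lower band reaches 0.5 to the first time the upper band does
    median_ci = c(lower = first_below(fit$lower),
                  upper = first_below(fit$upper)),
    all_censored = FALSE
  ), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  if (x$all_censored) {
    cat("<km_fit> all observations censored; median undefined\n")
  } else {
    cat(sprintf(
      "<km_fit> %d events; median %.4g (CI %.4g to %.4g)\n",
      x$n_events, x$median, x$median_ci[["lower"]], x$median_ci[["upper"]]
    ))
  }
  invisible(x)
}

#' Lifespan-versus-sleep regression with inclusion filters
#'
#' Ordinary least squares of lifespan on daily sleep with a full factorial
#' sex interaction (`lifespan ~ sleep * sex`), applied after the inclusion
#' filters: untreated (control) animals only, alive at least
#' `min_lifespan_days` days (removing the abnormal data preceding death),
#' and right-censored animals excluded. Sleep is the per-animal average over
#' the first days of recording (as stored in the cohort table). Per-sex
#' slopes are reported in days of life per hour of daily sleep, with basic
#' bootstrap confidence intervals from row resampling.
#'
#' @param cohort A `cohort_table` (see [simulate_cohort()]) or data frame
#'   with columns `sleep_h_per_day`, `lifespan_days`, `censored`, `sex`,
#'   `treatment`.
#' @param min_lifespan_days Minimum lifespan filter (default 20).
#' @param n_boot Bootstrap resamples for the slope CIs.
#' @param conf Confidence level.
#' @return List of class `lifespan_fit`: `coefficients`, `slopes` (per-sex
#'   slope with CI; `NA` when a sex is absent after filtering),
#'   `r_squared`, `n_used`, `audit` (rows removed by each filter).
#' @export
lifespan_regression <- function(cohort, min_lifespan_days = 20,
                                n_boot = 1000, conf = 0.95) {
  n0 <- nrow(cohort)
  untreated <- cohort$treatment %in% c("control", "untreated")
  d1 <- cohort[untreated, , drop = FALSE]
  lived <- d1$lifespan_days >= min_lifespan_days
  d2 <- d1[lived, , drop = FALSE]
  uncensored <- !d2$censored
  d <- d2[uncensored, , drop = FALSE]
  audit <- c(
    treated = n0 - nrow(d1),
    short_lived = nrow(d1) - nrow(d2),
    censored = nrow(d2) - nrow(d)
  )
  message(sprintf(
    "lifespan regression: %d/%d animals used (removed: %d treated, %d lived < %g d, %d censored)",
    nrow(d), n0, audit[["treated"]], audit[["short_lived"]], min_lifespan_days,
    audit[["censored"]]
  ))
  sexes <- c("female", "male")
  if (any(table(factor(d$sex, levels = sexes)) < 4 &
          table(factor(d$sex, levels = sexes)) > 0)) {
    stop("fewer than 4 animals in a sex after filtering")
  }
  d$sex <- factor(d$sex, levels = sexes)
  present <- sexes[sexes %in% unique(as.character(d$sex))]
  sl <- d$sleep_h_per_day
  lf <- d$lifespan_days
  sx <- as.character(d$sex)
  slope_fun <- function(idx) {
    out <- c(female = NA_real_, male = NA_real_)
    for (s in present) {
      i <- idx[sx[idx] == s]
      if (length(i) >= 2 && stats::var(sl[i]) > 0) {
        out[s] <- stats::cov(lf[i], sl[i]) / stats::var(sl[i])
      }
    }
    out
  }
  if (length(present) == 2) {
    fit <- stats::lm(lifespan_days ~ sleep_h_per_day * sex, data = d)
  } else {
    fit <- stats::lm(lifespan_days ~ sleep_h_per_day, data = d)
  }
  n <- nrow(d)
  est <- slope_fun(seq_len(n))
  boots <- matrix(NA_real_, n_boot, 2, dimnames = list(NULL, sexes))
  for (b in seq_len(n_boot)) {
    boots[b, ] <- slope_fun(sample.int(n, n, replace = TRUE))
  }
  a <- (1 - conf) / 2
  slopes <- data.frame(
    sex = sexes,
    slope = est[sexes],
    lower = NA_real_, upper = NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  for (k in 1:2) {
    bs <- boots[, k]
    bs <- bs[is.finite(bs)]
    if (length(bs) >= 100 && is.finite(est[sexes[k]])) {
      q <- stats::quantile(bs, c(a, 1 - a), names = FALSE)
      slopes$lower[k] <- 2 * est[sexes[k]] - q[2]
      slopes$upper[k] <- 2 * est[sexes[k]] - q[1]
    }
  }
  structure(list(
    coefficients = stats::coef(fit),
    slopes = slopes,
    r_squared = summary(fit)$r.squared,
    n_used = n,
    audit = audit
  ), class = "lifespan_fit")
}

#' @export
print.lifespan_fit <- function(x, ...) {
  cat(sprintf("<lifespan_fit> n = %d, R^2 = %.3f\n", x$n_used, x$r_squared))
  for (k in seq_len(nrow(x$slopes))) {
    s <- x$slopes[k, ]
    if (is.na(s$slope)) {
      cat(sprintf("  %s: slope unavailable\n", s$sex))
    } else {
      cat(sprintf("  %s: %+.3f days of life per hour of sleep (CI %.3f to %.3f)\n",
                  s$sex, s$slope, s$lower, s$upper))
    }
  }
  invisible(x)
}
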