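#' Control-calibrated sleep expectation
#'
#' Ordinary least squares of rebound-window sleep on baseline-window sleep in
#' the control group: `beta = Cov(R_C, B_C) / Var(B_C)`,
#' `alpha = mean(R_C) - beta * mean(B_C)`. The residuals of the controls have
#' exactly zero mean, which anchors the rebound statistic.
#'
#' @param baseline,rebound Numeric vectors of per-control sleep (minutes) in
#'   the baseline and rebound windows; at least 3 controls.
#' @return A list of class `sleep_expectation` with `alpha` (min), `beta`
#'   (dimensionless) and `n`.
#' @export
fit_control_expectation <- function(baseline, rebound) {
  stopifnot(length(baseline) == length(rebound))
  if (length(baseline) < 2) stop("need at least 2 control animals")
  vb <- stats::var(baseline)
  if (!is.finite(vb) || vb <= 0) stop("control baseline degenerate (zero variance)")
  beta <- stats::cov(rebound, baseline) / vb
  alpha <- mean(rebound) - beta * mean(baseline)
  structure(list(alpha = alpha, beta = beta, n = length(baseline)),
            class = "sleep_expectation")
}

#' @export
print.sleep_expectation <- function(x, ...) {
  cat(sprintf("<sleep_expectation> R-hat = %.4g + %.4g * B  (n = %d controls)\n",
              x$alpha, x$beta, x$n))
  invisible(x)
}

#' Homeostatic rebound statistic
#'
#' For each treated animal, the rebound excess is the measured rebound-window
#' sleep minus the sleep expected from its own baseline under the control
#' calibration: `H_i = R_i - (alpha + beta * B_i)`. The group mean carries a
#' basic-bootstrap confidence interval; a rebound is called significant when
#' that interval excludes 0 (estimation-based, no p-values).
#'
#' @param baseline,rebound Per-animal sleep (minutes) in the baseline and
#'   rebound windows. Animals with a missing value in either window are
#'   excluded (reported in the result).
#' @param expectation A [fit_control_expectation()] result (or a list with
#'   `alpha`, `beta`). When the control pairs themselves are supplied via
#'   `control_baseline`/`control_rebound`, the expectation is fitted here
#'   and the bootstrap resamples the controls as well, so the interval
#'   carries the calibration uncertainty — use this form for inference.
#' @param control_baseline,control_rebound Optional control-group window
#'   pairs (minutes).
#' @param n_boot Bootstrap resamples for the CI of the mean (default 1000).
#' @param conf Confidence level.
#' @return A list of class `rebound_result`: per-animal table (`B`, `R`,
#'   `R_hat`, `H`, minutes), `mean_h`, `ci`, `n`, `n_excluded`.
#' @export
sleep_rebound <- function(baseline, rebound, expectation = NULL,
                          control_baseline = NULL, control_rebound = NULL,
                          n_boot = 1000, conf = 0.95) {
  stopifnot(length(baseline) == length(rebound))
  full_boot <- !is.null(control_baseline)
  if (full_boot) {
    stopifnot(length(control_baseline) == length(control_rebound))
    expectation <- fit_control_expectation(control_baseline, control_rebound)
  } else if (is.null(expectation)) {
    stop("supply either an expectation or the control window pairs")
  }
  ok <- is.finite(baseline) & is.finite(rebound)
  n_excl <- sum(!ok)
  if (n_excl > 0) {
    message(sprintf("excluding %d animals missing a window", n_excl))
  }
  B <- baseline[ok]; R <- rebound[ok]
  R_hat <- expectation$alpha + expectation$beta * B
  H <- R - R_hat
  est <- mean(H)
  n <- length(H)
  a <- (1 - conf) / 2
  if (full_boot) {
    nc <- length(control_baseline)
    boots <- vapply(seq_len(n_boot), function(b) {
      ic <- sample.int(nc, nc, replace = TRUE)
      Bc <- control_baseline[ic]; Rc <- control_rebound[ic]
      vb <- stats::var(Bc)
      if (vb <= 0) return(NA_real_)
      bet <- stats::cov(Rc, Bc) / vb
      alp <- mean(Rc) - bet * mean(Bc)
      it <- sample.int(n, n, replace = TRUE)
      mean(R[it] - (alp + bet * B[it]))
    }, numeric(1))
    boots <- boots[is.finite(boots)]
    q <- stats::quantile(boots, c(a, 1 - a), names = FALSE)
    ci <- c(lower = 2 * est - q[2], upper = 2 * est - q[1])
  } else if (n >= 2) {
    bb <- bootstrap_ci(H, mean, n_boot = n_boot, conf = conf)
    ci <- c(lower = bb$lower, upper = bb$upper)
  } else {
    ci <- c(lower = NA_real_, upper = NA_real_)
  }
  structure(list(
    animals = data.frame(B = B, R = R, R_hat = R_hat, H = H),
    alpha = expectation$alpha, beta = expectation$beta,
    mean_h = est, ci = ci,
    significant = isTRUE(ci[["lower"]] > 0) | isTRUE(ci[["upper"]] < 0),
    n = n, n_excluded = n_excl
  ), class = "rebound_result")
}

#' @export
print.rebound_result <- function(x, ...) {
  cat(sprintf(
    "<rebound_result> mean H = %.2f min (95%% CI %.2f to %.2f), n = %d%s\n",
    x$mean_h, x$ci[["lower"]], x$ci[["upper"]], x$n,
    if (x$significant) " *" else ""
  ))
  invisible(x)
}

#' Baseline/rebound window pairs from ethograms
#'
#' Convenience extraction of the `(B_i, R_i)` pairs: sleep in the same ZT
#' window on a baseline day and on a rebound day, via [window_sleep_min()].
#'
#' @param ethograms List of [ethogram()] objects.
#' @param baseline_day,rebound_day Day indices (0-based, ZT0 boundaries).
#' @param window_zt Half-open ZT window in hours.
#' @return Data frame `animal_id`, `B`, `R` (minutes).
#' @export
rebound_windows <- function(ethograms, baseline_day, rebound_day,
                            window_zt = c(0, 3)) {
  data.frame(
    animal_id = vapply(ethograms, function(e) e$animal_id, ""),
    B = vapply(ethograms, window_sleep_min, 0, day = baseline_day,
               window_zt = window_zt),
    R = vapply(ethograms, window_sleep_min, 0, day = rebound_day,
               window_zt = window_zt),
    stringsAsFactors = FALSE
  )
}
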