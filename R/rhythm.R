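#' Bin stimulus events on a ZT-aligned grid
#'
#' Counts rotations in half-open bins of width `bin_h` hours whose edges sit
#' on zeitgeber-time multiples, zero-filling empty bins over the whole span.
#'
#' @param stim A `stimulus_log`.
#' @param bin_h Bin width in hours; must divide 24.
#' @param lights_on_s Offset of ZT0 in seconds.
#' @param span_s Length-2 recording span in seconds (default from the
#'   events, extended to whole bins).
#' @return Data frame `bin_start_s`, `zt_h`, `count`, with attributes
#'   `bin_h` and `period_bins` (bins per 24 h).
#' @export
rotation_counts <- function(stim, bin_h = 0.5, lights_on_s = 0,
                            span_s = NULL) {
  if (24 %% bin_h != 0) stop("bin_h must divide 24")
  bs <- bin_h * 3600
  if (is.null(span_s)) {
    hi <- if (nrow(stim)) max(stim$t_onset) + 1 else bs
    span_s <- c(0, hi)
  }
  first <- floor((span_s[1] - lights_on_s) / bs)
  last <- ceiling((span_s[2] - lights_on_s) / bs) - 1
  edges <- lights_on_s + (first:last) * bs
  k <- floor((stim$t_onset - lights_on_s) / bs)
  k <- k[k >= first & k <= last]
  counts <- tabulate(k - first + 1L, nbins = length(edges))
  structure(data.frame(
    bin_start_s = edges,
    zt_h = ((edges - lights_on_s) / 3600) %% 24,
    count = counts
  ), bin_h = bin_h, period_bins = as.integer(24 / bin_h),
  class = c("rotation_counts", "data.frame"))
}

#' Classical seasonal decomposition with variance fractions
#'
#' Additive decomposition of a regularly binned series into a periodic
#' (circadian, period = `period_bins` bins), long-range trend and residual
#' component: the trend is a centered moving average over one period, the
#' periodic component is the per-phase mean of the detrended series
#' re-centered to zero, and the residual is the remainder — so that
#' `observed = periodic + trend + residual` exactly wherever the trend is
#' defined. Variance fractions are `Var(component) / Var(observed)` on that
#' trimmed support, the definition under which the three fractions sum near
#' one.
#'
#' @param x Numeric series (e.g. `rotation_counts()$count`) of length >= 2
#'   periods, or a `rotation_counts` data frame.
#' @param period_bins Bins per period (taken from the attribute when `x` is
#'   a `rotation_counts`).
#' @return A list of class `decomposition`: `observed`, `periodic`, `trend`,
#'   `residual` (with `NA` at the trimmed edges), `fractions` (named
#'   `periodic`, `trend`, `residual`), `period_bins`, `degenerate`.
#' @export
seasonal_decompose <- function(x, period_bins = NULL) {
  if (inherits(x, "rotation_counts")) {
    if (is.null(period_bins)) period_bins <- attr(x, "period_bins")
    x <- x$count
  }
  if (is.null(period_bins)) stop("period_bins must be given")
  x <- as.numeric(x)
  if (length(x) < 2 * period_bins) {
    stop("series must span at least two periods")
  }
  dec <- stats::decompose(stats::ts(x, frequency = period_bins),
                          type = "additive")
  periodic <- as.numeric(dec$seasonal)
  trend <- as.numeric(dec$trend)
  resid <- as.numeric(dec$random)
  s <- !is.na(trend)
  vo <- stats::var(x[s])
  if (!is.finite(vo) || vo == 0) {
    fr <- c(periodic = 0, trend = 0, residual = 0)
    degenerate <- TRUE
  } else {
    fr <- c(
      periodic = stats::var(periodic[s]) / vo,
      trend = stats::var(trend[s]) / vo,
      residual = stats::var(resid[s]) / vo
    )
    degenerate <- FALSE
  }
  structure(list(
    observed = x, periodic = periodic, trend = trend, residual = resid,
    fractions = fr, period_bins = period_bins, degenerate = degenerate
  ), class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf(
    "<decomposition> %d bins, period %d%s\n  variance fractions: periodic %.3f, trend %.3f, residual %.3f\n",
    length(x$observed), x$period_bins,
    if (x$degenerate) " [degenerate: zero variance]" else "",
    x$fractions[["periodic"]], x$fractions[["trend"]], x$fractions[["residual"]]
  ))
  invisible(x)
}
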