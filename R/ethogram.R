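#' Epoch-level immobility from maximal velocity
#'
#' An epoch is immobile when its maximal velocity is strictly below the
#' threshold: `vmax < t_v`. The threshold is deliberately explicit everywhere
#' (no magic constant): it comes from the upstream tracker's validation, and
#' 1 mm/s is only this package's default.
#'
#' @param series A `tracking_series`, or a numeric vector of `vmax`.
#' @param t_v Velocity threshold, mm/s (> 0).
#' @return Logical vector, one flag per epoch.
#' @export
score_immobility <- function(series, t_v = 1) {
  if (!is.numeric(t_v) || length(t_v) != 1L || t_v <= 0) stop("t_v must be > 0")
  v <- if (is.data.frame(series)) series$vmax else series
  v < t_v
}

#' Mask epochs following stimulus onsets
#'
#' Data in the `mask_s` seconds following each rotation onset are not
#' considered for sleep scoring (the spinning tube produces spurious
#' velocity). Masked epochs are *neutral*: excluded from sleep totals but not
#' breaking an immobility run — treating them as mobile would abolish all
#' immobility under closed-loop deprivation by construction.
#'
#' @param series A `tracking_series` (provides the epoch grid).
#' @param stim A `stimulus_log` (or `NULL` for no stimuli).
#' @param mask_s Mask length from each onset, seconds (>= 0, default 6).
#' @return Logical vector: `TRUE` for epochs overlapping any
#'   `[onset, onset + mask_s)`.
#' @export
mask_stimuli <- function(series, stim, mask_s = 6) {
  if (mask_s < 0) stop("mask_s must be >= 0")
  E <- attr(series, "epoch_s")
  n <- nrow(series)
  masked <- logical(n)
  if (is.null(stim) || nrow(stim) == 0L || mask_s == 0) return(masked)
  t0 <- series$t[1]
  span <- c(t0, t0 + n * E)
  out <- stim$t_onset < span[1] | stim$t_onset >= span[2]
  if (any(out)) {
    warning(sprintf("%d stimulus onsets outside the recording span", sum(out)))
  }
  eps <- 1e-9
  for (on in stim$t_onset[!out]) {
    i1 <- max(1, floor((on - t0) / E + eps) + 1)
    i2 <- min(n, ceiling((on + mask_s - t0) / E - eps))
    if (i2 >= i1) masked[i1:i2] <- TRUE
  }
  masked
}

#' Sleep annotation by the five-minute rule
#'
#' Maximal runs of immobility (masked epochs are neutral: they neither count
#' toward nor break a run) whose *unmasked* immobile time is strictly greater
#' than `min_bout_s` are sleep bouts; the whole bout, including its first
#' 300 s, is scored asleep. Exactly 300 s of immobility is not sleep.
#'
#' @param immobile Logical epoch flags from [score_immobility()].
#' @param masked Logical epoch flags from [mask_stimuli()] (default none).
#' @param epoch_s Epoch length, seconds.
#' @param min_bout_s Threshold, seconds (default 300).
#' @return A list: `asleep` (logical per epoch; masked epochs are never
#'   flagged), and `bouts` (data frame `start_s`, `end_s`, `duration_s` of
#'   unmasked immobile time, in seconds from the start of the flag vector).
#' @export
annotate_sleep <- function(immobile, masked = rep(FALSE, length(immobile)),
                           epoch_s = 10, min_bout_s = 300) {
  stopifnot(length(masked) == length(immobile))
  n <- length(immobile)
  asleep <- logical(n)
  counts <- integer(0); starts <- integer(0); ends <- integer(0)
  brk <- !immobile & !masked
  r <- rle(brk)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (r$values[k]) next
    seg <- idx_start[k]:idx_end[k]
    live <- seg[immobile[seg] & !masked[seg]]
    if (!length(live)) next
    dur <- length(live) * epoch_s
    if (dur > min_bout_s) {
      asleep[live] <- TRUE
      counts <- c(counts, length(live))
      starts <- c(starts, live[1])
      ends <- c(ends, live[length(live)])
    }
  }
  list(
    asleep = asleep,
    bouts = data.frame(
      start_s = (starts - 1L) * epoch_s,
      end_s = ends * epoch_s,
      duration_s = counts * epoch_s
    )
  )
}

#' Minute-level behavioral states
#'
#' Each complete minute is classified by an ordered decision rule:
#' *quiescence* if every epoch in the minute has `vmax < t_v`; otherwise
#' *micromovement* if the total distance moved within the minute
#' (sum of absolute position differences at epoch resolution) is below
#' `t_d`; otherwise *walking*. The 15-mm default for `t_d` reflects the
#' bimodal distribution of per-minute distance that separates in-place
#' movement from locomotion. Incomplete trailing minutes are dropped.
#'
#' @param series A `tracking_series` with at least one complete minute.
#' @param t_v Immobility threshold, mm/s.
#' @param t_d Walking threshold on per-minute distance, mm (default 15).
#' @return Data frame: `minute`, `t_start`, `state` (factor with levels
#'   quiescence/micromovement/walking), `distance_mm`.
#' @export
classify_minutes <- function(series, t_v = 1, t_d = 15) {
  E <- attr(series, "epoch_s")
  epm <- 60 / E
  if (epm != round(epm) || epm < 1) {
    stop("epoch_s must divide 60 s for minute classification")
  }
  epm <- as.integer(epm)
  n_min <- nrow(series) %/% epm
  if (n_min < 1) stop("need at least one complete minute")
  use <- seq_len(n_min * epm)
  vm <- matrix(series$vmax[use], nrow = epm)
  xm <- matrix(series$x[use], nrow = epm)
  quiet <- colSums(vm < t_v) == epm
  dist <- if (epm > 1) colSums(abs(xm[-1, , drop = FALSE] - xm[-epm, , drop = FALSE])) else numeric(n_min)
  state <- ifelse(quiet, "quiescence", ifelse(dist < t_d, "micromovement", "walking"))
  data.frame(
    minute = seq_len(n_min) - 1L,
    t_start = series$t[1] + (seq_len(n_min) - 1L) * 60,
    state = factor(state, levels = .states),
    distance_mm = dist
  )
}

#' Normalize positions to the food--cotton axis
#'
#' `(x - Q0.01(x)) / Q0.99(x - Q0.01(x))`: position 0 at the food end, 1 at
#' the cotton end, using the 1st and 99th percentiles of the animal's own
#' full recording instead of min/max so that spurious detections beyond the
#' physical tube do not stretch the scale. Values may slightly exceed
#' `[0, 1]` by construction.
#'
#' @param series A `tracking_series` (or numeric positions) with >= 100
#'   epochs.
#' @return Numeric vector of normalized positions.
#' @export
normalize_position <- function(series) {
  x <- if (is.data.frame(series)) series$x else series
  if (length(x) < 100) stop("need >= 100 epochs for stable position quantiles")
  q1 <- stats::quantile(x, 0.01, names = FALSE)
  den <- stats::quantile(x - q1, 0.99, names = FALSE)
  if (den <= 0) stop("degenerate positional range")
  (x - q1) / den
}

#' Virtual activity-monitor re-scoring
#'
#' Re-scores a tracking series the way a legacy infrared beam device would
#' see it: activity is a midline crossing (sign change of `x - midline`
#' between consecutive epochs), immobility is the interval between
#' crossings, and the five-minute rule is applied to crossing-free runs.
#' Because crossings are a strict subset of movement, this can only
#' overestimate sleep relative to the velocity-based ethogram.
#'
#' @param series A `tracking_series`.
#' @param min_bout_s Sleep-rule threshold, seconds.
#' @return A list: `crossing` (logical per epoch), `asleep` (logical per
#'   epoch), `sleep_min_per_day`.
#' @export
vdam_rescore <- function(series, min_bout_s = 300) {
  E <- attr(series, "epoch_s")
  mid <- attr(series, "tube_length_mm") / 2
  side <- series$x >= mid
  n <- length(side)
  crossing <- c(FALSE, side[-1] != side[-n])
  ann <- annotate_sleep(!crossing, epoch_s = E, min_bout_s = min_bout_s)
  days <- n * E / 86400
  list(
    crossing = crossing,
    asleep = ann$asleep,
    sleep_min_per_day = sum(ann$asleep) * E / 60 / days
  )
}

#' Build a full ethogram from a tracking series
#'
#' One call wiring the scoring chain: immobility thresholding, stimulus
#' masking, the five-minute sleep rule, minute-level state classification and
#' position normalization.
#'
#' @param series A `tracking_series`.
#' @param stim Optional `stimulus_log` for this animal.
#' @param t_v,t_d,mask_s,min_bout_s Scoring parameters, see the individual
#'   functions.
#' @return An object of class `ethogram`: epoch flags (`immobile`, `masked`,
#'   `asleep`), sleep `bouts`, `minutes` (states + distance), normalized
#'   positions `pos_norm`, and the recording context.
#' @export
#' @examples
#' trk <- simulate_fly(sim_config(seed = 2, duration_h = 24))
#' eth <- ethogram(trk)
#' eth
ethogram <- function(series, stim = NULL, t_v = 1, t_d = 15, mask_s = 6,
                     min_bout_s = 300) {
  E <- attr(series, "epoch_s")
  immobile <- score_immobility(series, t_v)
  masked <- mask_stimuli(series, stim, mask_s)
  ann <- annotate_sleep(immobile, masked, epoch_s = E, min_bout_s = min_bout_s)
  minutes <- classify_minutes(series, t_v = t_v, t_d = t_d)
  pos_norm <- tryCatch(normalize_position(series), error = function(e) NULL)
  structure(list(
    animal_id = attr(series, "animal_id"),
    epoch = data.frame(
      t = series$t, immobile = immobile, masked = masked, asleep = ann$asleep
    ),
    bouts = data.frame(
      start_s = series$t[1] + ann$bouts$start_s,
      end_s = series$t[1] + ann$bouts$end_s,
      duration_s = ann$bouts$duration_s
    ),
    minutes = minutes,
    pos_norm = pos_norm,
    epoch_s = E,
    lights_on_s = attr(series, "lights_on_s"),
    params = list(t_v = t_v, t_d = t_d, mask_s = mask_s, min_bout_s = min_bout_s)
  ), class = "ethogram")
}

#' @export
print.ethogram <- function(x, ...) {
  n <- nrow(x$epoch)
  days <- n * x$epoch_s / 86400
  cat(sprintf(
    "<ethogram> %s: %.3g days; %d sleep bouts, %.1f min sleep/day\n",
    x$animal_id, days, nrow(x$bouts), sum(x$epoch$asleep) * x$epoch_s / 60 / days
  ))
  print(table(x$minutes$state))
  invisible(x)
}

#' Daily sleep and activity summary
#'
#' Aggregates an ethogram over its complete ZT days: total sleep per day, a
#' 48-bin (30-min) fraction-asleep profile on the ZT grid, micromovement and
#' walking minutes per day, distance walked per day, and mean normalized
#' position.
#'
#' @param eth An [ethogram()].
#' @return A one-row data frame of class `sleep_summary` with the
#'   `profile_30min` vector attached as an attribute.
#' @export
sleep_summary <- function(eth) {
  E <- eth$epoch_s
  rel <- eth$epoch$t - eth$lights_on_s
  day <- floor(rel / 86400)
  full_days <- as.numeric(names(which(table(day) == 86400 / E)))
  if (!length(full_days)) stop("need at least one complete ZT day")
  keep <- day %in% full_days
  nd <- length(full_days)
  ep <- eth$epoch[keep, , drop = FALSE]
  zt <- ((ep$t - eth$lights_on_s) / 3600) %% 24
  bin <- floor(zt * 2) # 48 half-hour bins
  unmasked <- !ep$masked
  prof <- vapply(0:47, function(b) {
    i <- bin == b & unmasked
    if (!any(i)) return(NA_real_)
    mean(ep$asleep[i])
  }, numeric(1))
  mrel <- eth$minutes$t_start - eth$lights_on_s
  mkeep <- floor(mrel / 86400) %in% full_days
  mm <- eth$minutes[mkeep, , drop = FALSE]
  out <- data.frame(
    animal_id = eth$animal_id,
    n_days = nd,
    sleep_min_per_day = sum(ep$asleep) * E / 60 / nd,
    micromovement_min_per_day = sum(mm$state == "micromovement") / nd,
    walking_min_per_day = sum(mm$state == "walking") / nd,
    walked_distance_mm_per_day =
      sum(mm$distance_mm[mm$state == "walking"]) / nd,
    mean_position = if (is.null(eth$pos_norm)) NA_real_ else
      mean(eth$pos_norm[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "profile_30min") <- prof
  class(out) <- c("sleep_summary", "data.frame")
  out
}

#' Sleep minutes within one ZT window of one day
#'
#' The window extraction used by the rebound analysis: minutes scored asleep
#' among unmasked epochs with `window_zt[1] <= ZT < window_zt[2]` on day
#' `day` (0-based, days start at ZT0).
#'
#' @param eth An [ethogram()].
#' @param day Day index.
#' @param window_zt Half-open ZT window in hours (default `c(0, 3)`).
#' @return Sleep in minutes.
#' @export
window_sleep_min <- function(eth, day, window_zt = c(0, 3)) {
  rel <- eth$epoch$t - eth$lights_on_s
  d <- floor(rel / 86400)
  zt <- (rel / 3600) %% 24
  i <- d == day & zt >= window_zt[1] & zt < window_zt[2] & !eth$epoch$masked
  sum(eth$epoch$asleep[i]) * eth$epoch_s / 60
}
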