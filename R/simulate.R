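# Alternating-bout engine. A bout's state is drawn with circadian-modulated
# weights (never repeating the previous state while an alternative has
# positive weight), its duration from a state-specific lognormal, and an
# optional closed-loop monitor interrupts quiescence bouts with tube
# rotations once continuous immobility reaches trigger_s.
#
# All randomness flows through the single R RNG stream in a fixed order
# (individual effect, then bouts, then epoch emission), which is what makes
# identical (seed, config) give bit-identical output.
simulate_bouts <- function(cfg, duration_s, trigger_s = Inf,
                           dep_start = 0, dep_end = Inf) {
  cap <- 1024L
  b_state <- integer(cap) # 1 q, 2 m, 3 w, 4 rotation
  b_start <- numeric(cap)
  b_end <- numeric(cap)
  nb <- 0L
  rot <- numeric(64L)
  nr <- 0L

  s_i <- if (cfg$indiv_quiescence_scale > 0) {
    exp(stats::rnorm(1, 0, cfg$indiv_quiescence_scale))
  } else 1
  bd <- cfg$bout_dur_params
  mls <- c(bd$quiescence[["meanlog"]] + log(s_i),
           bd$micromovement[["meanlog"]], bd$walking[["meanlog"]])
  sds <- c(bd$quiescence[["sdlog"]], bd$micromovement[["sdlog"]],
           bd$walking[["sdlog"]])
  wm_fac <- if (cfg$mated) cfg$mated_micromove_factor else 1
  w_q <- cfg$state_rates$quiescence
  w_m0 <- cfg$state_rates$micromovement * wm_fac
  w_w0 <- cfg$state_rates$walking
  amp <- cfg$circadian_amplitude
  kap <- cfg$peak_kappa
  lights <- cfg$lights_on_s
  monitored <- is.finite(trigger_s)

  t <- 0
  prev <- 0L
  while (t < duration_s) {
    cm <- if (amp > 0) {
      th <- 2 * pi * (((t - lights) / 3600) %% 24) / 24
      1 + amp * (exp(kap * (cos(th) - 1)) + exp(kap * (cos(th - pi) - 1)))
    } else 1
    w1 <- w_q; w2 <- w_m0 * cm; w3 <- w_w0 * cm
    if (prev == 1L) w1 <- 0 else if (prev == 2L) w2 <- 0
    else if (prev == 3L) w3 <- 0
    tot <- w1 + w2 + w3
    if (tot <= 0) {
      w1 <- w_q; w2 <- w_m0 * cm; w3 <- w_w0 * cm
      tot <- w1 + w2 + w3
      if (tot <= 0) stop("state_rates: all weights zero")
    }
    u <- stats::runif(1) * tot
    st <- if (u < w1) 1L else if (u < w1 + w2) 2L else 3L
    d <- exp(mls[st] + sds[st] * stats::rnorm(1))
    if (st == 1L && monitored) {
      rem <- d
      repeat {
        rot_at <- max(t, dep_start) + trigger_s
        bout_end <- t + rem
        if (rot_at >= bout_end || rot_at >= dep_end || rot_at >= duration_s) {
          if (nb == cap) {
            cap <- cap * 2L
            length(b_state) <- cap; length(b_start) <- cap; length(b_end) <- cap
          }
          nb <- nb + 1L
          b_state[nb] <- 1L; b_start[nb] <- t; b_end[nb] <- bout_end
          t <- bout_end
          prev <- 1L
          break
        }
        if (nb + 2L >= cap) {
          cap <- cap * 2L
          length(b_state) <- cap; length(b_start) <- cap; length(b_end) <- cap
        }
        nb <- nb + 1L
        b_state[nb] <- 1L; b_start[nb] <- t; b_end[nb] <- rot_at
        rem <- rem - (rot_at - t)
        t <- rot_at
        if (nr == length(rot)) length(rot) <- 2L * nr
        nr <- nr + 1L
        rot[nr] <- t
        nb <- nb + 1L
        b_state[nb] <- 4L; b_start[nb] <- t; b_end[nb] <- t + 1
        t <- t + 1
        if (stats::runif(1) < cfg$compliance) {
          if (cfg$startle_s > 0) {
            if (nb == cap) {
              cap <- cap * 2L
              length(b_state) <- cap; length(b_start) <- cap; length(b_end) <- cap
            }
            nb <- nb + 1L
            b_state[nb] <- 3L; b_start[nb] <- t; b_end[nb] <- t + cfg$startle_s
            t <- t + cfg$startle_s
          }
          prev <- 3L
          break
        }
        # non-compliant: bout continues, immobility clock restarts
      }
    } else {
      if (nb == cap) {
        cap <- cap * 2L
        length(b_state) <- cap; length(b_start) <- cap; length(b_end) <- cap
      }
      nb <- nb + 1L
      b_state[nb] <- st; b_start[nb] <- t; b_end[nb] <- t + d
      t <- t + d
      prev <- st
    }
  }

  keep <- which(b_start[seq_len(nb)] < duration_s)
  bouts <- data.frame(
    state = c(.states, "rotation")[b_state[keep]],
    start = b_start[keep],
    end = pmin(b_end[keep], duration_s)
  )
  rots <- rot[seq_len(nr)]
  list(bouts = bouts, rotations = rots[rots < duration_s], indiv_scale = s_i)
}

# Turn a bout sequence into epoch-level (t, x, vmax). Positions are sampled at
# epoch ends; vmax is the maximum over anything active within the epoch, so an
# epoch is mobile as soon as any part of an active bout touches it.
emit_epochs <- function(bouts, cfg, duration_s) {
  E <- cfg$epoch_s
  L <- cfg$tube_length_mm
  mid <- L / 2
  eps <- 1e-9
  nE <- floor(duration_s / E + eps)
  vmax <- stats::runif(nE, 0, 0.25)
  x <- numeric(nE)
  pos <- stats::runif(1, 0, L)
  fa <- min(1, cfg$food_attraction + if (cfg$mated) cfg$mated_food_shift else 0)

  ends_in <- function(s, e) {
    i1 <- floor(s / E + eps) + 1
    i2 <- floor(e / E + eps)
    if (i2 < i1) integer(0) else seq.int(max(1, i1), min(nE, i2))
  }
  overlapping <- function(s, e) {
    i1 <- floor(s / E + eps) + 1
    i2 <- ceiling(e / E - eps)
    if (i2 < i1) integer(0) else seq.int(max(1, i1), min(nE, i2))
  }

  for (b in seq_len(nrow(bouts))) {
    s <- bouts$start[b]; e <- bouts$end[b]; st <- bouts$state[b]
    idx <- ends_in(s, e)
    k <- length(idx)
    if (st == "quiescence") {
      if (k) x[idx] <- pos
    } else if (st == "rotation") {
      if (k) x[idx] <- pos
      ov <- overlapping(s, e)
      if (length(ov)) vmax[ov] <- pmax(vmax[ov], stats::runif(length(ov), 40, 80))
    } else if (st == "micromovement") {
      base <- if (stats::runif(1) < fa) stats::runif(1, 0, 4) else stats::runif(1, 4, L)
      if (k) {
        xb <- pmin(pmax(base + stats::runif(k, -0.5, 0.5), 0), L)
        x[idx] <- xb
        pos <- xb[k]
      } else {
        pos <- base
      }
      ov <- overlapping(s, e)
      if (length(ov)) vmax[ov] <- pmax(vmax[ov], stats::runif(length(ov), 1.2, 3))
    } else { # walking: bounce across the tube, crossing the midline
      if (k) {
        low_side <- pos >= mid # first sample lands on the opposite side
        sides <- if (k > 1) xor(low_side, (seq_len(k) - 1) %% 2 == 1) else low_side
        off <- stats::runif(k, 2, 8)
        xw <- ifelse(sides, off, L - off)
        x[idx] <- xw
        pos <- xw[k]
      } else {
        pos <- if (pos >= mid) stats::runif(1, 2, 8) else L - stats::runif(1, 2, 8)
      }
      ov <- overlapping(s, e)
      if (length(ov)) vmax[ov] <- pmax(vmax[ov], stats::runif(length(ov), 5, 20))
    }
  }
  data.frame(t = (seq_len(nE) - 1) * E, x = x, vmax = vmax)
}

#' Simulate one fly's tracking series
#'
#' Runs the alternating-bout process described in [sim_config()] and emits an
#' epoch-level tracking series: `t` (s, epoch-aligned), `x` (mm from the food
#' end) and `vmax` (mm/s, maximal velocity within the epoch). Quiescence
#' epochs have sub-threshold velocity and constant position; micromovement
#' epochs have supra-threshold velocity with per-minute displacement well
#' below the walking threshold, biased toward the food; walking epochs bounce
#' across the tube (crossing the midline, which is what a virtual activity
#' monitor can see).
#'
#' @param config A [sim_config()].
#' @param animal_id Identifier stored with the series.
#' @return A `tracking_series` data frame (`t`, `x`, `vmax`) with attributes
#'   `animal_id`, `epoch_s`, `tube_length_mm`, `lights_on_s`, plus the latent
#'   `bouts` table (ground truth for testing) and `indiv_scale`.
#' @export
#' @examples
#' trk <- simulate_fly(sim_config(seed = 7, duration_h = 24))
#' head(trk)
simulate_fly <- function(config, animal_id = "fly_001") {
  validate_sim_config(config)
  duration_s <- config$duration_h * 3600
  set.seed(config$seed)
  eng <- simulate_bouts(config, duration_s)
  ep <- emit_epochs(eng$bouts, config, duration_s)
  new_tracking_series(ep, config, animal_id,
                      bouts = eng$bouts, indiv_scale = eng$indiv_scale)
}

#' Simulate a fly under closed-loop sleep deprivation
#'
#' Same process as [simulate_fly()], monitored: whenever accumulated
#' continuous immobility reaches `trigger_s` (within the deprivation window),
#' a 1-s tube rotation is logged. With probability `compliance` the rotation
#' terminates the quiescence bout and the startled fly walks for
#' `startle_s` seconds; otherwise the bout continues and the immobility clock
#' restarts. The rotation spins the tube about its axis, so position is
#' unchanged while the tracked velocity spikes (those epochs are exactly what
#' [mask_stimuli()] masks downstream).
#'
#' @param config A [sim_config()].
#' @param trigger_s Immobility trigger in seconds; must exceed `epoch_s`.
#'   `Inf` is the no-deprivation sentinel: the stimulus log is empty and the
#'   series is identical to [simulate_fly()] under the same seed.
#' @param window_s Length-2 numeric: deprivation active on `[start, end)`
#'   seconds of the recording. Default the whole recording.
#' @param animal_id Identifier stored with the series and log.
#' @return A list with elements `series` (a `tracking_series`) and `stimuli`
#'   (a `stimulus_log` of rotation onsets, 1 s each).
#' @export
simulate_deprivation <- function(config, trigger_s, window_s = c(0, Inf),
                                 animal_id = "fly_001") {
  validate_sim_config(config)
  if (!is.numeric(trigger_s) || length(trigger_s) != 1L || trigger_s <= config$epoch_s) {
    stop("trigger_s must exceed epoch_s: the trigger is unresolvable at epoch resolution")
  }
  duration_s <- config$duration_h * 3600
  set.seed(config$seed)
  eng <- simulate_bouts(config, duration_s, trigger_s = trigger_s,
                        dep_start = window_s[1], dep_end = window_s[2])
  ep <- emit_epochs(eng$bouts, config, duration_s)
  series <- new_tracking_series(ep, config, animal_id,
                                bouts = eng$bouts, indiv_scale = eng$indiv_scale)
  list(
    series = series,
    stimuli = stimulus_log(animal_id, eng$rotations,
                           duration = rep(1, length(eng$rotations)))
  )
}

# Counter-based master-seed -> per-fly seed split: reproducible under
# appending new flies at the end only.
.fly_seed <- function(master, i) {
  as.integer((as.double(master %% 2147483647L) + i * 1000003) %% 2147483647)
}

# Latent (bout-level) scored sleep in seconds over [0, window_s]: total
# duration of quiescence bouts longer than min_bout_s, clipped to the window.
.latent_sleep_s <- function(bouts, window_s, min_bout_s = 300) {
  q <- bouts[bouts$state == "quiescence", , drop = FALSE]
  if (!nrow(q)) return(0)
  dur <- q$end - q$start
  keep <- dur > min_bout_s & q$start < window_s
  sum(pmin(q$end[keep], window_s) - q$start[keep])
}

#' Simulate a cohort with lifespans
#'
#' Generates `n` independent flies (per-fly seeds split from the master seed
#' with a counter, so a cohort is reproducible and stable under appending
#' flies), measures each fly's sleep over the first `sleep_window_days` days
#' from the latent bout sequence, and draws a lifespan from the sex-specific
#' Weibull shifted by `sleep_effect` days per hour of daily sleep, with
#' optional right-censoring.
#'
#' @param n Number of animals (>= 1).
#' @param config A [sim_config()]; its `seed` is the cohort master seed.
#' @param lifespan A [lifespan_config()].
#' @param treatment Label stored in the table (default `"control"`).
#' @param sleep_window_days Days over which daily sleep is averaged
#'   (default 10).
#' @param method `"bouts"` (default) scores each fly's sleep from its
#'   simulated latent bout sequence; `"analytic"` draws the per-fly sleep
#'   from the generator's own renewal-theory marginal (the individual's
#'   expected fraction given its quiescence scale, plus the sampling noise
#'   of a `sleep_window_days` average) — orders of magnitude faster, for
#'   large replicated cohort studies.
#' @return A `cohort_table` data frame: `animal_id`, `sex`, `treatment`,
#'   `sleep_min_per_day`, `sleep_h_per_day`, `lifespan_days`, `censored`.
#' @export
simulate_cohort <- function(n, config, lifespan = lifespan_config(),
                            treatment = "control", sleep_window_days = 10,
                            method = c("bouts", "analytic")) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  method <- match.arg(method)
  validate_sim_config(config)
  stopifnot(inherits(lifespan, "lifespan_config"))
  window_s <- sleep_window_days * 86400
  shape <- if (config$sex == "male") lifespan$male_shape else lifespan$female_shape
  scale <- if (config$sex == "male") lifespan$male_scale else lifespan$female_scale
  sleep_h <- numeric(n)
  life <- numeric(n)
  cens <- logical(n)
  mu_q0 <- config$bout_dur_params$quiescence[["meanlog"]]
  for (i in seq_len(n)) {
    set.seed(.fly_seed(config$seed, i))
    if (method == "bouts") {
      eng <- simulate_bouts(config, window_s)
      sleep_h[i] <- .latent_sleep_s(eng$bouts, window_s) / 3600 / sleep_window_days
    } else {
      s_i <- if (config$indiv_quiescence_scale > 0) {
        exp(stats::rnorm(1, 0, config$indiv_quiescence_scale))
      } else 1
      ci <- config
      ci$bout_dur_params$quiescence[["meanlog"]] <- mu_q0 + log(s_i)
      f <- expected_sleep_fraction(ci, grid = 48) +
        stats::rnorm(1, 0, 0.05 / sqrt(sleep_window_days))
      sleep_h[i] <- 24 * min(max(f, 0), 0.95)
    }
    base <- stats::rweibull(1, shape, scale)
    li <- max(base + lifespan$sleep_effect * sleep_h[i], 1e-3)
    if (stats::runif(1) < lifespan$censor_rate) {
      cens[i] <- TRUE
      li <- li * stats::runif(1, 0.3, 0.999)
    }
    life[i] <- li
  }
  structure(data.frame(
    animal_id = sprintf("fly_%04d", seq_len(n)),
    sex = config$sex,
    treatment = treatment,
    sleep_min_per_day = sleep_h * 60,
    sleep_h_per_day = sleep_h,
    lifespan_days = life,
    censored = cens,
    stringsAsFactors = FALSE
  ), class = c("cohort_table", "data.frame"))
}

#' Inject a sleep surplus into a ZT window of a tracking series
#'
#' Overwrites the leading epochs of one zeitgeber-time window with quiescence
#' so that the scored sleep in that window exceeds the unmodified series' own
#' scored sleep by exactly `extra_min` minutes (to epoch resolution). The
#' number of epochs overwritten accounts for the sleep the animal would have
#' obtained there anyway. Used to build rebound scenarios with a known
#' homeostatic surplus.
#'
#' @param series A `tracking_series`.
#' @param extra_min Surplus sleep to inject, minutes.
#' @param window_zt Length-2 ZT window in hours, half-open (default
#'   `c(0, 3)`).
#' @param day Day index (0-based, days start at ZT0) of the window.
#' @param t_v Immobility threshold (mm/s) used to compute the series' own
#'   sleep inside the window.
#' @param min_bout_s Sleep-rule threshold in seconds.
#' @param allow_partial An animal already asleep for most of the window has
#'   no headroom for the full surplus (a ceiling effect). `FALSE` (default)
#'   raises an error; `TRUE` fills the whole window with quiescence and
#'   records the achieved surplus in the `achieved_surplus_min` attribute.
#' @return The modified `tracking_series` (attribute `achieved_surplus_min`
#'   gives the surplus actually injected).
#' @export
inject_sleep_surplus <- function(series, extra_min, window_zt = c(0, 3),
                                 day = 1, t_v = 1, min_bout_s = 300,
                                 allow_partial = FALSE) {
  E <- attr(series, "epoch_s")
  lights <- attr(series, "lights_on_s")
  rel <- series$t - lights
  d <- floor(rel / 86400)
  zth <- (rel / 3600) %% 24
  idx <- which(d == day & zth >= window_zt[1] & zth < window_zt[2])
  if (!length(idx)) stop("requested ZT window not covered by the recording")
  imm <- score_immobility(series, t_v)
  asleep <- annotate_sleep(imm, epoch_s = E, min_bout_s = min_bout_s)$asleep
  surplus_s <- seq_along(idx) * E - cumsum(asleep[idx]) * E
  L <- which(surplus_s >= extra_min * 60)[1]
  if (is.na(L)) {
    if (!allow_partial) {
      stop("window too short to hold the requested sleep surplus")
    }
    L <- length(idx)
  }
  sel <- idx[seq_len(L)]
  series$x[sel] <- series$x[sel[1]]
  series$vmax[sel] <- 0.1
  attr(series, "achieved_surplus_min") <- surplus_s[L] / 60
  series
}
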