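.states <- c("quiescence", "micromovement", "walking")

#' Simulation configuration for a single tracked fly
#'
#' Builds the parameter set for the alternating-bout (semi-Markov) simulator.
#' A fly alternates between quiescence, micromovement and walking bouts; a
#' bout's state is drawn with weights that are modulated over the day by a
#' bimodal circadian drive (activity peaks at lights-on and lights-off), and
#' its duration is drawn from a state-specific lognormal. Quiescence durations
#' are heavy-tailed so that sleep bouts well beyond the 300-s rule, up to the
#' 1000-s immobility triggers used in deprivation protocols, occur naturally.
#'
#' By default the quiescence initiation weight is calibrated analytically (see
#' [calibrate_quiescence_weight()]) so that the expected scored sleep of the
#' median individual matches `target_sleep_min`: 618.5 min/day for males and
#' 299.2 min/day for females, the baseline means of the population this
#' simulator emulates. Passing `state_rates` explicitly disables calibration.
#'
#' @param seed Integer seed; identical seed + config gives bit-identical
#'   output.
#' @param sex `"female"` or `"male"`. Sets the default micromovement weight
#'   (females micromove substantially more) and the default sleep target.
#' @param duration_h Recording length in hours (>= 1).
#' @param epoch_s Epoch length in seconds (default 10).
#' @param tube_length_mm Tube length in mm, food end at 0 (default 70).
#' @param lights_on_s Offset of ZT0 (lights-on) in seconds relative to
#'   recording start. The simulator starts recordings at ZT0 by default.
#' @param circadian_amplitude Dimensionless >= 0 scaling of the bimodal
#'   activity drive; 0 emulates a clock mutant in constant darkness (flat
#'   activity profile).
#' @param peak_kappa Concentration of the two von Mises-shaped activity peaks.
#' @param state_rates Named list `quiescence`, `micromovement`, `walking` of
#'   strictly positive (or zero) bout-initiation weights. `NULL` (default)
#'   derives them from `sex` and `target_sleep_min`.
#' @param bout_dur_params Named list of `c(meanlog=, sdlog=)` lognormal
#'   duration parameters per state (seconds).
#' @param indiv_quiescence_scale Standard deviation (log scale) of the
#'   per-animal multiplicative random effect on quiescence durations; gives
#'   stable per-individual sleep propensity across recordings. 0 disables it.
#' @param food_attraction Probability that a micromovement bout is located
#'   within 4 mm of the food end.
#' @param mated Logical; mating switches behavior by multiplying the
#'   micromovement weight by `mated_micromove_factor` and shifting positional
#'   preference toward the food by `mated_food_shift`.
#' @param mated_micromove_factor,mated_food_shift Size of the mating switch.
#' @param compliance Probability in `[0, 1]` that a closed-loop tube rotation
#'   terminates the ongoing quiescence bout (1 = perfect deprivation).
#' @param startle_s Duration (s) of the forced walking bout that follows a
#'   rotation which terminates a quiescence bout; rotated flies run. Set to 0
#'   for an animal that re-enters quiescence immediately after each rotation.
#' @param target_sleep_min Daily sleep target in minutes used to calibrate the
#'   quiescence weight when `state_rates` is `NULL`; default 618.5 (male) or
#'   299.2 (female).
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_fly()], [simulate_deprivation()], [simulate_cohort()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, sex = "female", duration_h = 48)
#' cfg$state_rates$quiescence
sim_config <- function(seed = 1L,
                       sex = c("female", "male"),
                       duration_h = 120,
                       epoch_s = 10,
                       tube_length_mm = 70,
                       lights_on_s = 0,
                       circadian_amplitude = 1,
                       peak_kappa = 4,
                       state_rates = NULL,
                       bout_dur_params = NULL,
                       indiv_quiescence_scale = 0.8,
                       food_attraction = 0.5,
                       mated = FALSE,
                       mated_micromove_factor = 2.5,
                       mated_food_shift = 0.3,
                       compliance = 0.95,
                       startle_s = 25,
                       target_sleep_min = NULL) {
  sex <- match.arg(sex)
  if (is.null(bout_dur_params)) {
    bout_dur_params <- list(
      quiescence    = c(meanlog = log(400), sdlog = 1.1),
      micromovement = c(meanlog = log(60), sdlog = 0.6),
      walking       = c(meanlog = log(30), sdlog = 0.6)
    )
  }
  if (is.null(target_sleep_min)) {
    target_sleep_min <- if (sex == "male") 618.5 else 299.2
  }
  cfg <- structure(list(
    seed = as.integer(seed),
    sex = sex,
    duration_h = duration_h,
    epoch_s = epoch_s,
    tube_length_mm = tube_length_mm,
    lights_on_s = lights_on_s,
    circadian_amplitude = circadian_amplitude,
    peak_kappa = peak_kappa,
    state_rates = state_rates,
    bout_dur_params = bout_dur_params,
    indiv_quiescence_scale = indiv_quiescence_scale,
    food_attraction = food_attraction,
    mated = mated,
    mated_micromove_factor = mated_micromove_factor,
    mated_food_shift = mated_food_shift,
    compliance = compliance,
    startle_s = startle_s,
    target_sleep_min = target_sleep_min
  ), class = "sim_config")
  if (is.null(state_rates)) {
    w_m <- if (sex == "male") 0.55 else 1
    cfg$state_rates <- list(quiescence = 1, micromovement = w_m, walking = 1)
    cfg$state_rates$quiescence <-
      calibrate_quiescence_weight(cfg, target_sleep_min / 1440)
  }
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    stop(sprintf("invalid sim_config field '%s': %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field, lo = -Inf, strict = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      bad(field, "must be a single number")
    }
    if ((strict && v <= lo) || (!strict && v < lo)) {
      bad(field, sprintf("must be %s %g", if (strict) ">" else ">=", lo))
    }
  }
  num1("duration_h", 1)
  num1("epoch_s", 0, strict = TRUE)
  num1("tube_length_mm", 0, strict = TRUE)
  num1("circadian_amplitude", 0)
  num1("peak_kappa", 0, strict = TRUE)
  num1("indiv_quiescence_scale", 0)
  num1("startle_s", 0)
  if (!is.numeric(cfg$compliance) || length(cfg$compliance) != 1L ||
      is.na(cfg$compliance) || cfg$compliance < 0 || cfg$compliance > 1) {
    bad("compliance", "must be in [0, 1]")
  }
  if (!is.numeric(cfg$food_attraction) || cfg$food_attraction < 0 ||
      cfg$food_attraction > 1) {
    bad("food_attraction", "must be in [0, 1]")
  }
  if (!is.logical(cfg$mated) || length(cfg$mated) != 1L || is.na(cfg$mated)) {
    bad("mated", "must be TRUE or FALSE")
  }
  sr <- cfg$state_rates
  if (!is.list(sr) || !all(.states %in% names(sr))) {
    bad("state_rates", "must name quiescence, micromovement and walking")
  }
  w <- unlist(sr[.states])
  if (any(!is.finite(w)) || any(w < 0)) {
    bad("state_rates", "weights must be finite and >= 0")
  }
  if (sum(w) <= 0) bad("state_rates", "at least one weight must be > 0")
  bd <- cfg$bout_dur_params
  if (!is.list(bd) || !all(.states %in% names(bd))) {
    bad("bout_dur_params", "must name quiescence, micromovement and walking")
  }
  for (s in .states) {
    p <- bd[[s]]
    if (!all(c("meanlog", "sdlog") %in% names(p)) ||
        !all(is.finite(p)) || p[["sdlog"]] < 0) {
      bad("bout_dur_params", sprintf("state '%s' needs finite meanlog, sdlog >= 0", s))
    }
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> %s fly, %.5g h at %gs epochs, seed %d\n",
    x$sex, x$duration_h, x$epoch_s, x$seed
  ))
  w <- unlist(x$state_rates[.states])
  cat(sprintf("  state weights  q/m/w: %.4g / %.4g / %.4g\n", w[1], w[2], w[3]))
  cat(sprintf(
    "  circadian amplitude %.3g; compliance %.3g; mated %s\n",
    x$circadian_amplitude, x$compliance, x$mated
  ))
  invisible(x)
}

# Bimodal circadian multiplier on active-state initiation weights:
# 1 + A * (vonMises(zt; 0, kappa) + vonMises(zt; 12, kappa)), peaks scaled to 1.
circadian_mod <- function(zt, cfg) {
  a <- cfg$circadian_amplitude
  if (a == 0) return(rep(1, length(zt)))
  k <- cfg$peak_kappa
  th <- 2 * pi * zt / 24
  1 + a * (exp(k * (cos(th) - 1)) + exp(k * (cos(th - pi) - 1)))
}

# E[D], E[D * 1{D > c}] for a lognormal duration.
.lnorm_mean <- function(p) exp(p[["meanlog"]] + p[["sdlog"]]^2 / 2)
.lnorm_tail_mean <- function(p, c) {
  m <- p[["meanlog"]]; s <- p[["sdlog"]]
  if (s == 0) return(if (exp(m) > c) exp(m) else 0)
  exp(m + s^2 / 2) * stats::pnorm((m + s^2 - log(c)) / s)
}

# Stationary distribution of the embedded alternating-bout chain for weights w
# (transitions from i to j != i with probability w_j / sum_{k != i} w_k).
.embedded_stationary <- function(w) {
  active <- w > 0
  if (sum(active) == 1L) {
    p <- as.numeric(active)
    return(p)
  }
  P <- matrix(0, 3, 3)
  for (i in 1:3) {
    others <- setdiff(1:3, i)
    tot <- sum(w[others])
    if (tot > 0) P[i, others] <- w[others] / tot else P[i, i] <- 1
  }
  A <- rbind(diag(3) - t(P), rep(1, 3))
  pi_ <- qr.solve(A, c(0, 0, 0, 1))
  pi_[pi_ < 0] <- 0
  pi_ / sum(pi_)
}

#' Expected scored-sleep fraction under a configuration
#'
#' Analytic (renewal-theory) approximation of the long-run fraction of time
#' the five-minute rule scores as sleep, for the median individual
#' (per-animal quiescence scale 1). The circadian modulation is handled
#' quasi-statically: the local stationary sleep fraction is computed on a ZT
#' grid and averaged over the day (bouts are short relative to the 24-h
#' modulation, so the approximation error is small).
#'
#' @param cfg A [sim_config()].
#' @param quiescence_weight Optional override of the quiescence initiation
#'   weight (used internally during calibration).
#' @param min_bout_s Sleep rule threshold (strictly-greater-than), seconds.
#' @param grid Number of ZT grid points for the quasi-static average.
#' @return Expected fraction of time asleep, in `[0, 1]`.
#' @export
expected_sleep_fraction <- function(cfg, quiescence_weight = NULL,
                                    min_bout_s = 300, grid = 288) {
  w_q <- if (is.null(quiescence_weight)) cfg$state_rates$quiescence else quiescence_weight
  w_m0 <- cfg$state_rates$micromovement *
    (if (cfg$mated) cfg$mated_micromove_factor else 1)
  w_w0 <- cfg$state_rates$walking
  e_q <- .lnorm_mean(cfg$bout_dur_params$quiescence)
  e_qs <- .lnorm_tail_mean(cfg$bout_dur_params$quiescence, min_bout_s)
  e_m <- .lnorm_mean(cfg$bout_dur_params$micromovement)
  e_w <- .lnorm_mean(cfg$bout_dur_params$walking)
  zt <- seq(0, 24, length.out = grid + 1)[-(grid + 1)]
  cmod <- circadian_mod(zt, cfg)
  frac <- vapply(cmod, function(cm) {
    w <- c(w_q, w_m0 * cm, w_w0 * cm)
    if (w[1] <= 0) return(0)
    if (w[2] + w[3] <= 0) return(e_qs / e_q)
    pi_ <- .embedded_stationary(w)
    tot <- pi_[1] * e_q + pi_[2] * e_m + pi_[3] * e_w
    pi_[1] * e_qs / tot
  }, numeric(1))
  mean(frac)
}

#' Calibrate the quiescence weight to a target sleep fraction
#'
#' Solves for the quiescence bout-initiation weight at which
#' [expected_sleep_fraction()] equals `target_frac`, by monotone
#' root-finding. This is how sleep-amount "targets" are dialed into the
#' simulator without touching the bout-duration distributions.
#'
#' @param cfg A [sim_config()] (its current quiescence weight is ignored).
#' @param target_frac Target fraction of the day scored asleep, in `(0, 1)`.
#' @return The calibrated quiescence weight (scalar).
#' @export
calibrate_quiescence_weight <- function(cfg, target_frac) {
  if (!is.numeric(target_frac) || target_frac <= 0 || target_frac >= 1) {
    stop("target_frac must be in (0, 1)")
  }
  fmax <- expected_sleep_fraction(cfg, quiescence_weight = 1e9)
  if (target_frac >= fmax) {
    stop(sprintf(
      "target sleep fraction %.3f exceeds the attainable maximum %.3f under these bout durations",
      target_frac, fmax
    ))
  }
  f <- function(lw) expected_sleep_fraction(cfg, quiescence_weight = exp(lw)) - target_frac
  exp(stats::uniroot(f, c(log(1e-9), log(1e9)), tol = 1e-10)$root)
}

#' Cohort lifespan configuration
#'
#' Sex-specific Weibull lifespans, optionally shifted by daily sleep amount,
#' with right-censoring. The default scales put the control median lifespans
#' at 46.0 days (males) and 41.0 days (females); `sleep_effect` defaults to 0
#' (sleep amount does not causally shift lifespan), the null under which the
#' sleep-versus-lifespan regression is expected to find nothing.
#'
#' @param male_scale,female_scale Weibull scale (days) per sex.
#' @param male_shape,female_shape Weibull shape per sex (> 0).
#' @param sleep_effect Days of life added per hour of daily sleep.
#' @param censor_rate Fraction of animals right-censored, in `[0, 1)`.
#' @return An object of class `lifespan_config`.
#' @export
lifespan_config <- function(male_scale = 46 / log(2)^(1 / 5),
                            female_scale = 41 / log(2)^(1 / 5),
                            male_shape = 5,
                            female_shape = 5,
                            sleep_effect = 0,
                            censor_rate = 0) {
  bad <- function(field, why) {
    stop(sprintf("invalid lifespan_config field '%s': %s", field, why),
         call. = FALSE)
  }
  for (f in c("male_scale", "female_scale", "male_shape", "female_shape")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      bad(f, "must be a single number > 0")
    }
  }
  if (!is.numeric(sleep_effect) || length(sleep_effect) != 1L ||
      !is.finite(sleep_effect)) {
    bad("sleep_effect", "must be a single finite number")
  }
  if (!is.numeric(censor_rate) || censor_rate < 0 || censor_rate >= 1) {
    bad("censor_rate", "must be in [0, 1)")
  }
  structure(list(
    male_scale = male_scale, female_scale = female_scale,
    male_shape = male_shape, female_shape = female_shape,
    sleep_effect = sleep_effect, censor_rate = censor_rate
  ), class = "lifespan_config")
}
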