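# Independent brute-force oracles and scenario builders used across tests.

fseed <- ethosleep:::.fly_seed

# Brute-force five-minute-rule enumerator: walks the flag sequence epoch by
# epoch, accumulating unmasked immobile epochs into runs that only a mobile
# unmasked epoch can break. Independent of the rle-based implementation.
oracle_sleep <- function(immobile, masked, epoch_s = 10, min_bout_s = 300) {
  n <- length(immobile)
  asleep <- logical(n)
  run <- integer(0)
  flush <- function(run, asleep) {
    if (length(run) * epoch_s > min_bout_s) asleep[run] <- TRUE
    asleep
  }
  for (i in seq_len(n)) {
    if (masked[i]) next
    if (immobile[i]) {
      run <- c(run, i)
    } else {
      asleep <- flush(run, asleep)
      run <- integer(0)
    }
  }
  flush(run, asleep)
}

# Direct product-limit computation from first principles.
oracle_km <- function(time, censored) {
  ev_times <- sort(unique(time[!censored]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (k in seq_along(ev_times)) {
    tt <- ev_times[k]
    at_risk <- sum(time >= tt)
    d <- sum(time == tt & !censored)
    s <- s * (1 - d / at_risk)
    surv[k] <- s
  }
  median <- if (any(surv <= 0.5)) ev_times[which(surv <= 0.5)[1]] else NA_real_
  list(time = ev_times, surv = surv, median = median)
}

# A tracking series built directly from vectors (1 epoch = 10 s).
make_series <- function(x, vmax, animal_id = "t1", epoch_s = 10,
                        tube_length_mm = 70) {
  tracking_series(seq_along(x) * epoch_s - epoch_s, x, vmax, animal_id,
                  epoch_s, tube_length_mm = tube_length_mm)
}

# Minimal ethogram carrying only minute states, for distribution tests.
make_minute_ethogram <- function(states, animal_id = "m1", lights_on_s = 0) {
  structure(list(
    animal_id = animal_id,
    minutes = data.frame(
      minute = seq_along(states) - 1L,
      t_start = (seq_along(states) - 1L) * 60,
      state = factor(states, levels = c("quiescence", "micromovement", "walking")),
      distance_mm = 0
    ),
    lights_on_s = lights_on_s
  ), class = "ethogram")
}

# Two behaviorally polarized cohorts: a mated-like micromover phenotype and
# a walker phenotype, separated by their bout-type parameters (short
# quiescence bouts shared so both are moderate sleepers).
make_phenotype_config <- function(seed, major, ...) {
  rates <- list(quiescence = 1, micromovement = 0, walking = 0)
  rates[[major]] <- 1
  sim_config(
    seed = seed, sex = "female", duration_h = 96,
    indiv_quiescence_scale = 0.15, state_rates = rates,
    bout_dur_params = list(
      quiescence = c(meanlog = log(150), sdlog = 1.1),
      micromovement = c(meanlog = log(60), sdlog = 0.6),
      walking = c(meanlog = log(30), sdlog = 0.6)
    ), ...
  )
}

# Quarter-day activity profile of one fly (fraction of minutes active per
# ZT hour bin), used by the uniformity checks.
hourly_activity_profile <- function(cfg) {
  eth <- ethogram(simulate_fly(cfg))
  act <- eth$minutes$state != "quiescence"
  bin <- floor((eth$minutes$t_start / 3600) %% 24)
  tapply(act, bin, mean)
}

# Circular-shift permutation test of profile flatness: under a flat
# (time-homogeneous) process each fly's daily profile is phase-invariant, so
# randomly rotating profiles preserves the null distribution of the
# across-fly mean profile's variance while respecting within-fly
# autocorrelation.
profile_flatness_pvalue <- function(profiles, n_perm = 499) {
  nb <- nrow(profiles)
  stat <- function(m) stats::var(rowMeans(m))
  s0 <- stat(profiles)
  sp <- vapply(seq_len(n_perm), function(r) {
    shifted <- vapply(seq_len(ncol(profiles)), function(j) {
      k <- sample.int(nb, 1)
      profiles[((seq_len(nb) - 1 + k) %% nb) + 1, j]
    }, numeric(nb))
    stat(shifted)
  }, numeric(1))
  (1 + sum(sp >= s0)) / (n_perm + 1)
}
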