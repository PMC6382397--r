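test_that("identical seed and config give bit-identical output", {
  cfg <- sim_config(seed = 7, sex = "female", duration_h = 24)
  a <- simulate_fly(cfg)
  b <- simulate_fly(cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  da <- simulate_deprivation(cfg, 60)
  db <- simulate_deprivation(cfg, 60)
  expect_identical(as.data.frame(da$series), as.data.frame(db$series))
  expect_identical(da$stimuli$t_onset, db$stimuli$t_onset)
})

test_that("zero quiescence weight abolishes scored sleep", {
  cfg <- sim_config(seed = 2, duration_h = 24,
                    state_rates = list(quiescence = 0, micromovement = 1,
                                       walking = 1))
  eth <- ethogram(simulate_fly(cfg))
  expect_equal(sum(eth$epoch$asleep), 0)
})

test_that("a perfectly compliant immediate re-sleeper is rotated floor(3600/21) times per hour", {
  cfg <- sim_config(
    seed = 3, duration_h = 1, compliance = 1, startle_s = 0,
    indiv_quiescence_scale = 0, circadian_amplitude = 0,
    state_rates = list(quiescence = 1, micromovement = 0, walking = 0),
    bout_dur_params = list(
      quiescence = c(meanlog = log(5000), sdlog = 0),
      micromovement = c(meanlog = log(60), sdlog = 0.6),
      walking = c(meanlog = log(30), sdlog = 0.6)
    )
  )
  sim <- simulate_deprivation(cfg, 20)
  expect_equal(nrow(sim$stimuli), 171) # 20 s immobility + 1 s rotation cycles
})

test_that("an infinite trigger is the no-deprivation sentinel", {
  cfg <- sim_config(seed = 11, sex = "female", duration_h = 24)
  plain <- simulate_fly(cfg)
  dep <- simulate_deprivation(cfg, Inf)
  expect_identical(as.data.frame(plain), as.data.frame(dep$series))
  expect_equal(nrow(dep$stimuli), 0)
})

test_that("a trigger at or below epoch resolution is rejected", {
  cfg <- sim_config(seed = 1, duration_h = 24)
  expect_error(simulate_deprivation(cfg, 10), "epoch")
  expect_error(simulate_deprivation(cfg, 5), "epoch")
})

test_that("every rotation is preceded by exactly the trigger of continuous immobility", {
  cfg <- sim_config(seed = 13, sex = "female", duration_h = 24,
                    compliance = 0.5) # exercise clock restarts too
  trig <- 45
  sim <- simulate_deprivation(cfg, trig)
  bouts <- attr(sim$series, "bouts")
  expect_gt(nrow(sim$stimuli), 10)
  for (on in sim$stimuli$t_onset) {
    prevb <- bouts[abs(bouts$end - on) < 1e-9, ]
    expect_equal(nrow(prevb), 1)
    expect_equal(prevb$state, "quiescence")
    # immobility accumulated since bout start or last rotation end
    expect_equal(on - prevb$start, trig, tolerance = 1e-9)
  }
})

test_that("cohorts are reproducible, censor-free when asked, and size-checked", {
  cfg <- sim_config(seed = 21, sex = "male", duration_h = 24)
  a <- simulate_cohort(1, cfg, lifespan_config(), sleep_window_days = 2)
  b <- simulate_cohort(1, cfg, lifespan_config(), sleep_window_days = 2)
  expect_identical(a, b)
  expect_error(simulate_cohort(0, cfg), "n must be")
  co <- simulate_cohort(25, cfg, lifespan_config(censor_rate = 0),
                        sleep_window_days = 2)
  expect_false(any(co$censored))
  expect_true(all(co$lifespan_days > 0))
  # appending flies does not change earlier rows
  co30 <- simulate_cohort(30, cfg, lifespan_config(censor_rate = 0),
                          sleep_window_days = 2)
  expect_equal(co30$sleep_min_per_day[1:25], co$sleep_min_per_day)
})

test_that("analytic cohorts agree with bout-level cohorts", {
  cfg <- sim_config(seed = 5, sex = "male")
  a <- simulate_cohort(40, cfg, lifespan_config())
  b <- simulate_cohort(40, cfg, lifespan_config(), method = "analytic")
  expect_gt(cor(a$sleep_min_per_day, b$sleep_min_per_day), 0.9)
  expect_lt(abs(mean(a$sleep_min_per_day) - mean(b$sleep_min_per_day)), 60)
})

test_that("female configurations micromove more than male configurations", {
  mm <- vapply(1:8, function(i) {
    eth <- ethogram(simulate_fly(sim_config(seed = fseed(31, i), sex = "male",
                                            duration_h = 48)))
    sleep_summary(eth)$micromovement_min_per_day
  }, numeric(1))
  ff <- vapply(1:8, function(i) {
    eth <- ethogram(simulate_fly(sim_config(seed = fseed(32, i), sex = "female",
                                            duration_h = 48)))
    sleep_summary(eth)$micromovement_min_per_day
  }, numeric(1))
  expect_gt(mean(ff), mean(mm))
})

test_that("the mating switch increases micromovement and shifts flies toward food", {
  un <- lapply(1:6, function(i) {
    sleep_summary(ethogram(simulate_fly(
      sim_config(seed = fseed(41, i), sex = "female", duration_h = 48)
    )))
  })
  ma <- lapply(1:6, function(i) {
    sleep_summary(ethogram(simulate_fly(
      sim_config(seed = fseed(41, i), sex = "female", duration_h = 48,
                 mated = TRUE)
    )))
  })
  expect_gt(mean(vapply(ma, function(s) s$micromovement_min_per_day, 0)),
            mean(vapply(un, function(s) s$micromovement_min_per_day, 0)))
  expect_lt(mean(vapply(ma, function(s) s$mean_position, 0)),
            mean(vapply(un, function(s) s$mean_position, 0)))
})

test_that("a flat circadian drive yields a uniform activity profile, a modulated one does not", {
  set.seed(401)
  flat <- vapply(1:10, function(i) {
    hourly_activity_profile(sim_config(seed = fseed(7, i), sex = "female",
                                       duration_h = 240,
                                       circadian_amplitude = 0))
  }, numeric(24))
  expect_gt(profile_flatness_pvalue(flat), 0.01)
  mod <- vapply(1:6, function(i) {
    hourly_activity_profile(sim_config(seed = fseed(8, i), sex = "female",
                                       duration_h = 120))
  }, numeric(24))
  expect_lt(profile_flatness_pvalue(mod), 0.01)
})

test_that("injected sleep surplus raises window sleep by the requested amount", {
  cfg <- sim_config(seed = 77, sex = "female", duration_h = 48)
  trk <- simulate_fly(cfg)
  eth0 <- ethogram(trk)
  base <- window_sleep_min(eth0, 1, c(0, 3))
  trk2 <- inject_sleep_surplus(trk, 40, c(0, 3), day = 1)
  eth2 <- ethogram(trk2)
  expect_equal(window_sleep_min(eth2, 1, c(0, 3)) - base, 40, tolerance = 5)
  # other windows untouched
  expect_equal(window_sleep_min(eth2, 0, c(0, 3)), window_sleep_min(eth0, 0, c(0, 3)))
})
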