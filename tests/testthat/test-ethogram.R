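test_that("immobility uses a strict velocity threshold", {
  s <- make_series(x = rep(1, 5), vmax = c(0, 0.5, 1, 1.5, 0.99))
  expect_equal(score_immobility(s, t_v = 1), c(TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_error(score_immobility(s, t_v = 0), "t_v")
  # element-wise oracle on random input
  set.seed(1)
  v <- runif(500, 0, 2)
  expect_identical(score_immobility(v, 1), vapply(v, function(z) z < 1, TRUE))
})

test_that("stimulus masking covers the seconds following each onset", {
  s <- make_series(x = rep(1, 30), vmax = rep(0, 30))
  expect_equal(mask_stimuli(s, NULL), rep(FALSE, 30))
  stim <- stimulus_log("t1", 100)
  m <- mask_stimuli(s, stim, mask_s = 6)
  expect_equal(which(m), 11) # the epoch covering [100, 110)
  # a mask reaching into the next epoch
  m2 <- mask_stimuli(s, stimulus_log("t1", 95), mask_s = 6)
  expect_equal(which(m2), c(10, 11))
  expect_warning(mask_stimuli(s, stimulus_log("t1", 1e6)), "outside")
  # dense rotations against an interval-overlap oracle
  ons <- seq(5, 280, by = 20)
  md <- mask_stimuli(s, stimulus_log("t1", ons), mask_s = 6)
  oracle <- vapply(seq_len(30), function(i) {
    a <- (i - 1) * 10; b <- i * 10
    any(ons < b & (ons + 6) > a)
  }, TRUE)
  expect_identical(md, oracle)
})

test_that("the five-minute rule is strict at 300 s and keeps whole bouts", {
  # exactly 300 s of immobility is not sleep
  imm <- c(rep(TRUE, 30), FALSE)
  ann <- annotate_sleep(imm, epoch_s = 10, min_bout_s = 300)
  expect_equal(sum(ann$asleep), 0)
  # 600 s is one complete sleep bout, first 300 s included
  imm2 <- c(rep(TRUE, 60), FALSE)
  ann2 <- annotate_sleep(imm2, epoch_s = 10)
  expect_equal(sum(ann2$asleep), 60)
  expect_equal(ann2$bouts$duration_s, 600)
})

test_that("sleep annotation matches the brute-force enumerator on random flag sequences", {
  set.seed(2024)
  for (r in 1:200) {
    n <- 120
    imm <- runif(n) < runif(1, 0.3, 0.9)
    masked <- if (r %% 2 == 0) runif(n) < 0.1 else rep(FALSE, n)
    ann <- annotate_sleep(imm, masked, epoch_s = 10, min_bout_s = 300)
    expect_identical(ann$asleep, oracle_sleep(imm, masked))
  }
})

test_that("sleep is monotone in both thresholds", {
  set.seed(9)
  trk <- simulate_fly(sim_config(seed = 15, sex = "female", duration_h = 24))
  sleep_at <- function(tv, mb) {
    sum(annotate_sleep(score_immobility(trk, tv), epoch_s = 10,
                       min_bout_s = mb)$asleep)
  }
  tvs <- c(0.2, 0.5, 1, 2, 6)
  expect_true(all(diff(vapply(tvs, sleep_at, 0, mb = 300)) >= 0))
  mbs <- c(60, 180, 300, 600, 1200)
  expect_true(all(diff(vapply(mbs, sleep_at, 0, tv = 1)) <= 0))
})

test_that("minute classification follows the ordered rule with a 15-mm walking threshold", {
  # all epochs quiet, constant position -> quiescence
  q <- classify_minutes(make_series(rep(5, 6), rep(0, 6)))
  expect_equal(as.character(q$state), "quiescence")
  # one mobile epoch, 10 mm total displacement -> micromovement
  s_m <- make_series(c(5, 10, 15, 15, 15, 15), c(0, 2, 0, 0, 0, 0))
  m <- classify_minutes(s_m)
  expect_equal(as.character(m$state), "micromovement")
  expect_equal(m$distance_mm, 10)
  # 20 mm total displacement -> walking
  s_w <- make_series(c(5, 15, 25, 25, 25, 25), c(0, 3, 3, 0, 0, 0))
  expect_equal(as.character(classify_minutes(s_w)$state), "walking")
  # displacement exactly at the threshold is walking (strict "<" for micromovement)
  s_b <- make_series(c(5, 20, 20, 20, 20, 20), c(0, 3, 0, 0, 0, 0))
  expect_equal(as.character(classify_minutes(s_b)$state), "walking")
  # incomplete trailing minute dropped
  expect_equal(nrow(classify_minutes(make_series(rep(1, 10), rep(0, 10)))), 1)
})

test_that("minute states partition all complete minutes", {
  eth <- ethogram(simulate_fly(sim_config(seed = 33, sex = "female",
                                          duration_h = 24)))
  expect_equal(nrow(eth$minutes), 24 * 60)
  expect_false(anyNA(eth$minutes$state))
  expect_equal(sum(table(eth$minutes$state)), 24 * 60)
})

test_that("position normalization is quantile-based and affine-equivariant", {
  set.seed(4)
  x <- runif(5000, 0, 70)
  p <- normalize_position(x)
  expect_equal(mean(p >= 0 & p <= 1), 0.98, tolerance = 0.01)
  expect_equal(normalize_position(3 * x + 7), p)
  expect_error(normalize_position(rep(5, 200)), "degenerate")
  expect_error(normalize_position(runif(50)), "100 epochs")
})

test_that("virtual beam re-scoring sees only midline crossings", {
  # oscillating 1 mm around the food end: no crossings, vDAM sleeps all day
  n <- 8640
  osc <- make_series(rep(c(1, 2), n / 2), rep(c(2, 2), n / 2))
  vd <- vdam_rescore(osc)
  expect_equal(vd$sleep_min_per_day, 1440)
  expect_false(any(vd$crossing))
  # crossing the midline each minute: no vDAM sleep
  walk <- make_series(rep(c(rep(10, 3), rep(60, 3)), n / 6), rep(8, n))
  vw <- vdam_rescore(walk)
  expect_equal(vw$sleep_min_per_day, 0)
})

test_that("daily summaries aggregate on the ZT grid", {
  n <- 8640
  asleep_all <- make_series(rep(5, n), rep(0, n))
  s <- sleep_summary(ethogram(asleep_all))
  expect_equal(s$sleep_min_per_day, 1440)
  expect_equal(s$micromovement_min_per_day, 0)
  prof <- attr(s, "profile_30min")
  expect_equal(length(prof), 48)
  expect_true(all(prof == 1))
  # walking-only fly has no micromovement
  cfgw <- sim_config(seed = 5, duration_h = 24,
                     state_rates = list(quiescence = 0, micromovement = 0,
                                        walking = 1))
  sw <- sleep_summary(ethogram(simulate_fly(cfgw)))
  expect_equal(sw$micromovement_min_per_day, 0)
  expect_equal(sw$sleep_min_per_day, 0)
})

test_that("window sleep extraction respects day and ZT bounds", {
  # 2 days; immobile only during ZT1-2 of day 1
  n <- 2 * 8640
  v <- rep(5, n)
  day1_zt1 <- (86400 + 3600) / 10 + seq_len(360)
  v[day1_zt1] <- 0
  eth <- ethogram(make_series(rep(5, n), v))
  expect_equal(window_sleep_min(eth, 1, c(0, 3)), 60)
  expect_equal(window_sleep_min(eth, 0, c(0, 3)), 0)
  expect_equal(window_sleep_min(eth, 1, c(2, 3)), 0)
})
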