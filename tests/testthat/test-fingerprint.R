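test_that("behavioral distributions are per-interval state fractions", {
  # an all-quiescent fly is (1, 0, 0) in every interval
  cfgq <- sim_config(seed = 5, duration_h = 24,
                     state_rates = list(quiescence = 1, micromovement = 0,
                                        walking = 0))
  bq <- behavior_distribution(ethogram(simulate_fly(cfgq)))
  expect_equal(dim(bq), c(96, 3))
  expect_true(all(bq[, "quiescence"] == 1))
  # a uniform q/m/w cycle is the centroid in every interval
  eth <- make_minute_ethogram(rep(c("quiescence", "micromovement", "walking"),
                                  480))
  bc <- behavior_distribution(eth)
  expect_true(all(abs(bc - 1 / 3) < 1e-12))
  expect_true(all(abs(rowSums(bc) - 1) < 1e-9))
})

test_that("distributions match a direct per-interval counting oracle", {
  eth <- ethogram(simulate_fly(sim_config(seed = 51, sex = "female",
                                          duration_h = 48)))
  bd <- behavior_distribution(eth)
  zt <- (eth$minutes$t_start / 3600) %% 24
  iv <- floor(zt * 4)
  for (tt in c(0, 17, 48, 95)) {
    sub <- eth$minutes$state[iv == tt]
    expect_equal(unname(bd[tt + 1, ]),
                 as.numeric(table(sub) / length(sub)))
  }
})

test_that("Bhattacharyya coefficient and distance follow their definitions", {
  p <- c(0.25, 0.25, 0.5)
  expect_equal(bhattacharyya(p, p), list(bc = 1, bd = 0))
  d <- bhattacharyya(c(1, 0, 0), c(0, 1, 0))
  expect_equal(d$bc, 0)
  expect_equal(d$bd, -log(1e-6)) # capped at BD_max
  h <- bhattacharyya(c(0.25, 0.25, 0.5), c(0.5, 0.25, 0.25))
  expect_equal(h$bc, sqrt(0.125) + 0.25 + sqrt(0.125))
  expect_equal(h$bd, -log(sqrt(0.125) + 0.25 + sqrt(0.125)))
  expect_error(bhattacharyya(c(0.5, 0.4), c(0.5, 0.5)), "probability")
})

test_that("the Bhattacharyya distance is a divergence, not a metric", {
  bd <- function(p, q) bhattacharyya(p, q)$bd
  p <- c(0.3, 0.3, 0.4); q <- c(0.4, 0.3, 0.3); r <- c(0.5, 0.3, 0.2)
  expect_equal(bd(p, q), bd(q, p))
  expect_equal(bd(p, p), 0)
  expect_gt(bd(p, r), bd(p, q) + bd(q, r)) # triangle inequality fails
})

test_that("the pairwise matrix is the mean interval distance, symmetric, label-stable", {
  set.seed(61)
  dists <- lapply(1:5, function(i) {
    m <- matrix(rexp(96 * 3), 96)
    m <- m / rowSums(m)
    structure(m, class = "behavior_distribution")
  })
  names(dists) <- paste0("a", 1:5)
  D <- pairwise_distance(dists)
  expect_equal(diag(D), rep(0, 5), ignore_attr = TRUE)
  expect_equal(unclass(D), t(unclass(D)), ignore_attr = TRUE)
  # brute-force double loop
  for (i in 1:4) for (j in (i + 1):5) {
    ref <- mean(vapply(1:96, function(tt) {
      -log(max(sum(sqrt(dists[[i]][tt, ] * dists[[j]][tt, ])), 1e-6))
    }, numeric(1)))
    expect_equal(D[i, j], ref)
  }
  # permuting animals permutes rows/columns consistently
  Dp <- pairwise_distance(dists[c(3, 1, 5, 2, 4)])
  expect_equal(unclass(Dp), unclass(D)[c(3, 1, 5, 2, 4), c(3, 1, 5, 2, 4)],
               ignore_attr = TRUE)
  expect_equal(pairwise_distance(dists[c(1, 1)])[1, 2], 0)
})

test_that("UPGMA is exact on ultrametric input and matches the reference implementation", {
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  u2 <- upgma(d2)
  expect_equal(u2$height, 2)
  # ultrametric 4-leaf matrix: cophenetic distances reproduce the input
  U <- matrix(c(0, 2, 6, 6,
                2, 0, 6, 6,
                6, 6, 0, 4,
                6, 6, 4, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  uu <- upgma(U)
  expect_equal(as.matrix(stats::cophenetic(uu))[letters[1:4], letters[1:4]], U)
  # random matrices against hclust average linkage
  set.seed(71)
  for (r in 1:5) {
    m <- as.matrix(stats::dist(matrix(runif(36), 6)))
    dimnames(m) <- list(letters[1:6], letters[1:6])
    mine <- upgma(m)
    ref <- stats::hclust(stats::as.dist(m), method = "average")
    expect_equal(sort(mine$height), sort(ref$height))
    expect_equal(as.matrix(stats::cophenetic(mine)),
                 as.matrix(stats::cophenetic(ref))[mine$labels, mine$labels])
  }
  expect_error(upgma(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
  expect_error(upgma(matrix(0, 1, 1)), "2 leaves")
})

test_that("ternary coordinates are barycentric with an exact inverse", {
  tri <- structure(rbind(c(1, 0, 0), c(1 / 3, 1 / 3, 1 / 3), c(0, 0, 1)),
                   class = "behavior_distribution")
  tt <- ternary_trajectory(tri)
  expect_equal(unlist(tt[1, c("x", "y")]), c(x = 0, y = 0)) # quiescence vertex
  expect_equal(unlist(tt[2, c("x", "y")]), c(x = 0.5, y = sqrt(3) / 6))
  expect_equal(unlist(tt[3, c("x", "y")]), c(x = 0.5, y = sqrt(3) / 2))
  # inverse barycentric map recovers the probabilities
  pw <- tt$y / (sqrt(3) / 2)
  pm <- tt$x - pw / 2
  pq <- 1 - pm - pw
  expect_equal(cbind(pq, pm, pw), unclass(tri), ignore_attr = TRUE)
})
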