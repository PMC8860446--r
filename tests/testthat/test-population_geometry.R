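# Build a small fake tensor directly: rate[unit, cond, trial, bin].
make_tensor <- function(rate, odors = NULL, concs = NULL) {
  d <- dim(rate)
  odors <- odors %||% sprintf("o%d", seq_len(d[2]))
  concs <- concs %||% rep(1, d[2])
  structure(list(
    rate = rate,
    units = data.frame(unit_id = sprintf("u%d", seq_len(d[1])),
                       recording = 1),
    conditions = data.frame(odor_id = odors, concentration = concs,
                            key = paste(odors, concs),
                            stringsAsFactors = FALSE),
    time = (seq_len(d[4]) - 0.5) * 0.001, window = c(0, d[4] * 0.001),
    bin = 0.001), class = "response_tensor")
}

two_recordings <- function() {
  cfg <- tiny_config()
  a <- aligned_session(cfg, seed = 1)
  b <- aligned_session(cfg, seed = 2)
  list(list(raster = a$raster, trials = a$trials, units = a$session$units),
       list(raster = b$raster, trials = b$trials, units = b$session$units))
}

test_that("pseudopopulation concatenates units across recordings", {
  recs <- two_recordings()
  tens <- build_pseudopopulation(recs, bin = 0.01, seed = 1)
  n1 <- length(attr(recs[[1]]$raster, "units"))
  n2 <- length(attr(recs[[2]]$raster, "units"))
  expect_equal(dim(tens$rate)[1], n1 + n2)
  expect_equal(nrow(tens$units), n1 + n2)
})

test_that("trial pairing is reproducible under a fixed seed", {
  recs <- two_recordings()
  a <- build_pseudopopulation(recs, bin = 0.01, seed = 5)
  b <- build_pseudopopulation(recs, bin = 0.01, seed = 5)
  expect_identical(a$rate, b$rate)
  c <- build_pseudopopulation(recs, bin = 0.01, seed = 6)
  expect_false(identical(a$rate, c$rate))
})

test_that("single-recording pairing is the identity", {
  recs <- two_recordings()[1]
  tens <- build_pseudopopulation(recs, bin = 0.01, seed = 3)
  # recompute rates directly: trials in stored order per condition
  raster <- recs[[1]]$raster
  trials <- recs[[1]]$trials
  trials <- trials[trials$trial_id %in% attr(raster, "trial_ids"), ]
  key <- paste(trials$odor_id, trials$concentration)
  ci <- 2
  ids <- trials$trial_id[key == tens$conditions$key[ci]]
  for (k in c(1, 3)) {
    sel <- raster$trial_id == ids[k] &
      raster$unit_id == attr(raster, "units")[1] &
      raster$rel_time_s >= -0.1 & raster$rel_time_s < -0.09
    expect_equal(tens$rate[1, ci, k, 1], sum(sel) / 0.01)
  }
})

test_that("rank-3 data is fully explained by three components", {
  set.seed(4)
  n_units <- 8
  base <- matrix(rnorm(n_units * 3), n_units, 3)
  d <- c(n_units, 4, 2, 30)
  w <- array(rnorm(prod(c(3, d[2], d[4]))), c(3, d[2], d[4]))
  rate <- array(0, d)
  for (ci in seq_len(d[2])) for (bi in seq_len(d[4])) {
    v <- base %*% w[, ci, bi]
    rate[, ci, , bi] <- v  # identical trials
  }
  traj <- pca_trajectories(make_tensor(rate), K = 3)
  expect_equal(sum(traj$explained[1:3]), 1, tolerance = 1e-9)
  expect_true(all(diff(traj$explained) <= 1e-12))
  # loadings are orthonormal
  expect_equal(crossprod(traj$loadings), diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("identical conditions give coincident trajectories", {
  set.seed(5)
  one <- array(rnorm(6 * 1 * 3 * 20), c(6, 1, 3, 20))
  rate <- array(0, c(6, 3, 3, 20))
  for (ci in 1:3) rate[, ci, , ] <- one[, 1, , ]
  traj <- pca_trajectories(make_tensor(rate), K = 2)
  expect_equal(traj$scores[1, , ], traj$scores[2, , ], tolerance = 1e-9)
  dd <- euclidean_distance_timecourse(traj, cbind(1, 2:3))
  expect_true(all(abs(dd$distance) < 1e-9))
})

test_that("two-unit toy projections match a hand-computed PCA", {
  # two units, two conditions, one bin; observations are the 2 condition
  # means; PCA of two points: PC1 along their difference
  rate <- array(0, c(2, 2, 1, 1))
  rate[, 1, 1, 1] <- c(1, 0)
  rate[, 2, 1, 1] <- c(0, 2)
  traj <- pca_trajectories(make_tensor(rate), K = 2)
  dif <- c(1, -2) / sqrt(5)
  # scores are centred projections: +/- half the distance between points
  half <- sqrt(sum((c(1, 0) - c(0, 2))^2)) / 2
  expect_equal(abs(traj$scores[1, 1, 1]), half, tolerance = 1e-9)
  expect_equal(abs(sum(traj$loadings[, 1] * dif)), 1, tolerance = 1e-9)
  expect_error(pca_trajectories(make_tensor(rate), K = 3), "fewer units")
})

test_that("distance time course reproduces hand-enumerated pairs", {
  # constant-offset construction: distance equals the offset norm
  rate <- array(0, c(3, 2, 2, 5))
  rate[, 1, , ] <- 1
  rate[, 2, , ] <- 1
  rate[1, 2, , ] <- 1 + 3  # offset vector (3, 0, 0), norm 3
  traj <- pca_trajectories(make_tensor(rate), K = 3)
  dd <- euclidean_distance_timecourse(traj, matrix(c(1, 2), 1))
  expect_equal(dd$distance, rep(3, 5), tolerance = 1e-9)

  # three conditions with hand-set scores at one bin
  traj2 <- traj
  traj2$scores <- array(0, c(3, 1, 3))
  traj2$scores[1, 1, ] <- c(0, 0, 0)
  traj2$scores[2, 1, ] <- c(3, 4, 0)   # dist to 1: 5
  traj2$scores[3, 1, ] <- c(0, 0, 2)   # dist to 1: 2; to 2: sqrt(29)
  traj2$time <- 0.0005
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3))
  dd2 <- euclidean_distance_timecourse(traj2, pairs)
  expect_equal(dd2$distance, mean(c(5, 2, sqrt(29))), tolerance = 1e-12)
  expect_error(euclidean_distance_timecourse(traj2, pairs[0, ]), "empty")
})

test_that("distances are invariant to joint rotation of scores", {
  set.seed(6)
  rate <- array(rnorm(5 * 4 * 2 * 10), c(5, 4, 2, 10))
  traj <- pca_trajectories(make_tensor(rate), K = 3)
  dd <- euclidean_distance_timecourse(traj)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- traj
  for (ci in seq_len(dim(traj$scores)[1]))
    rot$scores[ci, , ] <- traj$scores[ci, , ] %*% t(R)
  dd_rot <- euclidean_distance_timecourse(rot)
  expect_equal(dd$distance, dd_rot$distance, tolerance = 1e-9)
})

test_that("condition pair selection distinguishes identity and intensity", {
  conds <- expand.grid(odor_id = c("o1", "o2"), concentration = c(0.5, 1),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conds$key <- paste(conds$odor_id, conds$concentration)
  idp <- condition_pairs(conds, "identity")
  expect_equal(nrow(idp), 2)  # o1-o2 at each concentration
  inp <- condition_pairs(conds, "intensity")
  expect_equal(nrow(inp), 2)  # 0.5-1 within each odor
  expect_equal(nrow(condition_pairs(conds, "all")), 6)
})

test_that("identity distances peak early and relax on generator data", {
  cfg <- separable_config()
  out <- aligned_session(cfg)
  recs <- list(list(raster = out$raster, trials = out$trials))
  tens <- build_pseudopopulation(recs, window = c(-0.1, 0.3), bin = 0.001,
                                 seed = 1)
  traj <- pca_trajectories(tens, K = 3)
  dd <- euclidean_distance_timecourse(
    traj, condition_pairs(traj$conditions, "identity"))
  pk <- dd$t_s[which.max(dd$distance)]
  expect_gte(pk, 0)
  expect_lt(pk, 0.135)  # response bump + kernel width
  late <- mean(dd$distance[dd$t_s >= 0.2])
  expect_lt(late, max(dd$distance) / 2)
})
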