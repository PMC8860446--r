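test_that("SDF of an empty train is identically zero", {
  s <- sdf_single(numeric(0), c(-0.1, 0.3))
  expect_true(all(s$rate == 0))
})

test_that("a single spike peaks at 1/(sigma*sqrt(2*pi))", {
  s <- sdf_single(0.1005, c(0, 0.3), sigma = 0.010)  # at a bin centre
  expect_equal(max(s$rate), 1 / (0.010 * sqrt(2 * pi)), tolerance = 1e-9)
  expect_equal(s$time[which.max(s$rate)], 0.1005)
})

test_that("SDF integrates to the spike count away from edges", {
  set.seed(1)
  times <- runif(40, 0.05, 0.25)
  s <- sdf_single(times, c(-0.2, 0.5), sigma = 0.010, grid_step = 0.001)
  expect_equal(sum(s$rate) * 0.001, 40, tolerance = 40 * 0.001)
})

test_that("SDF rejects non-positive sigma", {
  expect_error(sdf_single(0.1, c(0, 1), sigma = 0), "positive")
  expect_error(sdf_single(0.1, c(0, 1), sigma = -1), "positive")
})

test_that("SDF is linear in spike trains", {
  a <- c(0.05, 0.12)
  b <- c(0.08, 0.2, 0.21)
  sa <- sdf_single(a, c(0, 0.3))
  sb <- sdf_single(b, c(0, 0.3))
  sab <- sdf_single(c(a, b), c(0, 0.3))
  expect_equal(sab$rate, sa$rate + sb$rate, tolerance = 1e-12)
})

test_that("trial-averaged SDF matches per-trial computation", {
  out <- aligned_session(tiny_config())
  sdf <- spike_density(out$raster, out$trials)
  # recompute one unit x condition by hand from the raster
  u <- sdf$units[2]
  cond <- sdf$conditions[3, ]
  ids <- out$trials$trial_id[out$trials$valid &
                               out$trials$odor_id == cond$odor_id &
                               !is.na(out$trials$concentration) &
                               out$trials$concentration ==
                                 cond$concentration]
  spikes <- out$raster$rel_time_s[out$raster$unit_id == u &
                                    out$raster$trial_id %in% ids]
  # snap spikes to the bin centres the array implementation uses
  snapped <- -0.1 + (floor((spikes + 0.1) / 0.001) + 0.5) * 0.001
  manual <- sdf_single(snapped, c(-0.1, 0.3))$rate / length(ids)
  expect_lt(max(abs(as.numeric(sdf$rate[2, 3, ]) - manual)), 1e-9)
})

test_that("windowed rate counts spikes over the window length", {
  raster <- structure(
    data.frame(unit_id = "u1", trial_id = "t1",
               rel_time_s = c(0.06, 0.07, 0.12)),
    class = c("aligned_raster", "data.frame"), window = c(-0.1, 0.3),
    units = "u1", trial_ids = "t1")
  expect_equal(window_rate(raster, c(0.05, 0.10))$rate, 40)  # 2 / 0.05
  # spike exactly at the upper edge is excluded (half-open)
  raster$rel_time_s <- c(0.06, 0.10, 0.12)
  expect_equal(window_rate(raster, c(0.05, 0.10))$rate, 20)
  # empty train
  r0 <- raster[0, ]
  attributes(r0) <- attributes(raster)[c("class", "window", "units",
                                         "trial_ids")]
  expect_equal(window_rate(r0, c(0.05, 0.10))$rate, 0)
  expect_error(window_rate(raster, c(0.1, 0.1)), "lo < hi")
})

test_that("activated_units detects a uniform shift and not a null", {
  set.seed(2)
  blank <- matrix(rpois(25 * 2, 3), 25, 2, dimnames = list(NULL, c("a", "b")))
  same <- activated_units(blank, blank)
  expect_false(any(same$activated))
  shifted <- blank + 10
  up <- activated_units(shifted, blank)
  expect_true(all(up$activated))
  expect_equal(up$delta_rate, c(10, 10))
})

test_that("activated_units flags underpowered input", {
  res <- activated_units(matrix(1:2, 2, 1), matrix(0:1, 2, 1))
  expect_true(is.na(res$p))
  expect_true(is.na(res$activated))
})

test_that("activation test type-I error is near alpha under the null", {
  # equal-rate Poisson odor and blank rates, 1080 unit-odor pairs
  set.seed(7)
  n_pairs <- 1080
  odor <- matrix(rpois(25 * n_pairs, 2), 25, n_pairs)
  blank <- matrix(rpois(25 * n_pairs, 2), 25, n_pairs)
  res <- activated_units(odor, blank, alpha = 0.05)
  frac <- mean(res$activated)
  ci <- 2.576 * sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(frac - 0.05), ci + 0.01)  # discreteness slack
})

test_that("lifetime sparseness matches hand-evaluated cases", {
  expect_equal(lifetime_sparseness(c(2, 1, 0, 0)), 11 / 15)
  expect_equal(lifetime_sparseness(c(-1, 2)), 1)  # clipping rule
  expect_equal(lifetime_sparseness(c(5, rep(0, 10))), 1)
  expect_equal(lifetime_sparseness(rep(3, 11)), 0)
  expect_true(is.na(lifetime_sparseness(c(0, 0, -2))))
  expect_error(lifetime_sparseness(3), "at least two")
})

test_that("sparseness is scale-invariant and bounded in [0, 1]", {
  set.seed(3)
  for (i in 1:50) {
    r <- rnorm(sample(2:12, 1), 1, 2)
    s <- lifetime_sparseness(r)
    if (is.na(s)) next
    expect_gte(s, 0)
    expect_lte(s, 1 + 1e-12)
    expect_equal(lifetime_sparseness(r * 7.3), s, tolerance = 1e-12)
  }
})

test_that("responsive histogram covers trivial extremes", {
  act <- expand.grid(unit_id = c("u1", "u2"), odor_id = c("o1", "o2", "o3"),
                     stringsAsFactors = FALSE)
  act$concentration <- 1
  act$activated <- FALSE
  h0 <- responsive_count_histogram(act)
  expect_equal(h0$histogram$n_units, c(2, 0, 0, 0))
  expect_true(all(h0$per_odor$percent == 0))
  act$activated <- TRUE
  h1 <- responsive_count_histogram(act)
  expect_equal(h1$histogram$n_units, c(0, 0, 0, 2))
  expect_true(all(h1$per_odor$percent == 100))
  expect_equal(sum(h1$histogram$n_units), 2)
})

test_that("mean responsive count tracks the programmed response rate", {
  cfg <- generator_config(n_units = c(fan = 60, pyramidal = 0, untuned = 0),
                          n_odors = 8, concentrations = 1,
                          trials_per_condition = 12, response_prob = 0.3,
                          amplitude_mean = 40, amplitude_sd = 0)
  out <- aligned_session(cfg, seed = 21)
  act <- activation_matrix(out$raster, out$trials)
  cnt <- tapply(act$activated, act$unit_id, sum, na.rm = TRUE)
  # binomial mean 8 * 0.3 = 2.4 responsive odors per unit
  se <- sqrt(8 * 0.3 * 0.7 / length(cnt))
  expect_lt(abs(mean(cnt) - 2.4), 4 * se + 0.2)
})

test_that("identical trials give a perfect odd/even rank-order ridge", {
  # same spikes on every trial: even-trial peak equals the odd sort key
  trials <- data.frame(trial_id = sprintf("t%02d", 1:8),
                       odor_id = rep(c("o1", "o2"), each = 4),
                       concentration = 1,
                       odor_on_s = seq_len(8), t0_s = seq_len(8) + 0.1,
                       valid = TRUE)
  lat <- c(o1 = 0.08, o2 = 0.15)
  rows <- do.call(rbind, lapply(1:8, function(i) {
    data.frame(unit_id = "u1", trial_id = trials$trial_id[i],
               rel_time_s = lat[[trials$odor_id[i]]])
  }))
  raster <- structure(rows, class = c("aligned_raster", "data.frame"),
                      window = c(-0.1, 0.3), units = "u1",
                      trial_ids = trials$trial_id)
  ro <- rank_order_crossval(raster, trials)
  expect_equal(ro$pairs$odd_peak_s, ro$pairs$even_peak_s)
  expect_lt(max(abs(ro$pairs$odd_peak_s - unname(lat[order(lat)]))), 0.001)
  ridge <- apply(ro$matrix, 1, function(r) ro$time[which.max(r)])
  expect_equal(ridge, ro$pairs$odd_peak_s)
})

test_that("odd/even peak times correlate for programmed latencies", {
  cfg <- generator_config(n_units = c(fan = 25, pyramidal = 0, untuned = 0),
                          n_odors = 2, concentrations = 1,
                          trials_per_condition = 25, response_prob = 1,
                          amplitude_mean = 40, amplitude_sd = 0,
                          latency_sd = 0.05, response_width = 0.015)
  out <- aligned_session(cfg, seed = 31)
  ro <- rank_order_crossval(out$raster, out$trials)
  expect_gt(cor(ro$pairs$odd_peak_s, ro$pairs$even_peak_s,
                method = "spearman"), 0.9)
})

test_that("time-randomized spikes decorrelate odd and even peaks", {
  out <- aligned_session(tiny_config())
  raster <- out$raster
  set.seed(5)
  raster$rel_time_s <- runif(nrow(raster), -0.1, 0.3)
  ro <- rank_order_crossval(raster, out$trials)
  r <- cor(ro$pairs$odd_peak_s, ro$pairs$even_peak_s, method = "spearman")
  # permutation null: |rho| below ~3/sqrt(n)
  expect_lt(abs(r), 3 / sqrt(nrow(ro$pairs)))
})

test_that("early-only responses give early >> late activation", {
  cfg <- generator_config(n_units = c(fan = 40),
                          n_odors = 3, concentrations = 1,
                          trials_per_condition = 15, response_prob = 0.6,
                          amplitude_mean = 40, amplitude_sd = 0,
                          latency_mean = c(fan = 0.06),
                          latency_sd = 0.005, response_width = 0.01)
  out <- aligned_session(cfg, seed = 41)
  fr <- early_late_fractions(out$raster, out$trials)
  early <- mean(fr$percent[fr$phase == "early"])
  late <- mean(fr$percent[fr$phase == "late"])
  expect_gt(early, 40)
  expect_lt(late, 15)  # near type-I level
})
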