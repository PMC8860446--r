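# Minimal spike_density-like object with programmed rate curves.
make_sdf <- function(rates, odors, concs, time = seq(0.0005, 0.2995,
                                                     by = 0.001)) {
  n_units <- dim(rates)[1]
  structure(list(
    time = time, rate = rates,
    units = sprintf("u%d", seq_len(n_units)),
    conditions = data.frame(cond_id = seq_along(odors), odor_id = odors,
                            concentration = concs,
                            n_trials = 10,
                            key = paste(odors, concs),
                            stringsAsFactors = FALSE),
    sigma = 0.01, grid_step = 0.001, window = c(0, 0.3)),
    class = "spike_density")
}

bump <- function(time, centre, width = 0.01, amp = 10) {
  amp * exp(-((time - centre)^2) / (2 * width^2))
}

test_that("peak time and rate are extracted with the earliest-tie rule", {
  time <- seq(0.0005, 0.2995, by = 0.001)
  rates <- array(0, c(1, 2, length(time)))
  rates[1, 1, ] <- bump(time, 0.080)
  rates[1, 2, ] <- bump(time, 0.060) + bump(time, 0.120)  # equal maxima
  sdf <- make_sdf(rates, odors = c("o1", "o2"), concs = c(1, 1))
  pk <- peak_stats(sdf)
  expect_lt(abs(pk$peak_time_s[1] - 0.080), 0.001)
  expect_equal(pk$peak_rate[1], 10, tolerance = 0.01)  # grid discretization
  expect_lt(abs(pk$peak_time_s[2] - 0.060), 0.001)  # earliest of the ties
  expect_error(peak_stats(sdf, search_window = c(0.5, 0.6)),
               "empty search window")
})

test_that("programmed generator latency is recovered within 5 ms", {
  cfg <- generator_config(n_units = c(fan = 12),
                          n_odors = 2, concentrations = 1,
                          trials_per_condition = 25, response_prob = 1,
                          amplitude_mean = 30, amplitude_sd = 0,
                          latency_mean = c(fan = 0.075), latency_sd = 0,
                          latency_shift_per_doubling = c(fan = 0),
                          rate_gain_per_doubling = c(fan = 1))
  out <- aligned_session(cfg, seed = 17)
  sdf <- spike_density(out$raster, out$trials)
  pk <- peak_stats(sdf)
  # population mean recovers the latency tightly; single pairs are
  # kernel-and-sampling limited
  expect_lt(abs(mean(pk$peak_time_s) - 0.075), 0.003)
  expect_lt(max(abs(pk$peak_time_s - 0.075)), 0.030)
})

test_that("concentration trends report Spearman rho on pooled pairs", {
  time <- seq(0.0005, 0.2995, by = 0.001)
  concs <- c(0.25, 0.5, 1)
  # peak time strictly decreasing with concentration for every unit
  rates <- array(0, c(4, 3, length(time)))
  for (ui in 1:4) for (ci in 1:3)
    rates[ui, ci, ] <- bump(time, 0.120 - 0.02 * ci + 0.005 * ui)
  sdf <- make_sdf(rates, odors = rep("o1", 3), concs = concs)
  pk <- peak_stats(sdf)
  tr <- concentration_trend(pk, "peak_time")
  # tied concentration ranks bound |rho| below 1 even for a perfectly
  # monotone relation; -0.94 is the attainable extreme here
  expect_lt(tr$rho, -0.9)
  expect_lt(tr$p, 0.01)
  # a single pair across concentrations (no ties) reaches exactly -1
  one <- pk[pk$unit_id == "u1", ]
  expect_equal(suppressWarnings(
    cor(one$concentration, one$peak_time_s, method = "spearman")), -1)
})

test_that("a constant variable yields an undefined (flagged) trend", {
  time <- seq(0.0005, 0.2995, by = 0.001)
  rates <- array(0, c(5, 2, length(time)))
  for (ui in 1:5) for (ci in 1:2) rates[ui, ci, ] <- bump(time, 0.1)
  sdf <- make_sdf(rates, odors = rep("o1", 2), concs = c(0.5, 1))
  pk <- peak_stats(sdf)
  expect_warning(tr <- concentration_trend(pk, "peak_time"), "constant")
  expect_true(is.na(tr$rho))
})

test_that("independent peak times give a null trend", {
  set.seed(8)
  pk <- data.frame(unit_id = rep(sprintf("u%d", 1:50), each = 4),
                   odor_id = "o1",
                   concentration = rep(c(0.25, 0.33, 0.5, 1), 50),
                   peak_time_s = runif(200, 0.05, 0.15),
                   peak_rate = 10, activated = TRUE)
  tr <- concentration_trend(pk, "peak_time")
  expect_lt(abs(tr$rho), 3 / sqrt(tr$n))
  expect_gt(tr$p, 0.01)
})

test_that("pairwise peak-time differences match hand enumeration", {
  pk <- data.frame(unit_id = c("a", "b", "c"), odor_id = "o1",
                   concentration = 1,
                   peak_time_s = c(0.010, 0.020, 0.040),
                   peak_rate = 1, activated = TRUE)
  d <- pairwise_peak_time_diff(pk)
  expect_equal(d$mean_abs_diff_s, 0.020)  # (10+30+20)/3 ms
  expect_equal(d$n_pairs, 3)
  pk$peak_time_s <- rep(0.05, 3)
  expect_equal(pairwise_peak_time_diff(pk)$mean_abs_diff_s, 0)
})

test_that("within-odor averaging differs from pooling across odors", {
  pk <- data.frame(unit_id = rep(c("a", "b"), 2),
                   odor_id = rep(c("o1", "o2"), each = 2),
                   concentration = 1,
                   peak_time_s = c(0.01, 0.02, 0.10, 0.14),
                   peak_rate = 1, activated = TRUE)
  within <- pairwise_peak_time_diff(pk)
  expect_equal(within$mean_abs_diff_s, mean(c(0.01, 0.04)))
  pooled <- pairwise_peak_time_diff(pk, pool_odors = TRUE)
  expect_gt(pooled$mean_abs_diff_s, within$mean_abs_diff_s)
})

test_that("cross-population synchrony reflects programmed offsets", {
  a <- data.frame(unit_id = sprintf("a%d", 1:3), odor_id = "o1",
                  concentration = rep(c(0.5, 1), each = 3),
                  peak_time_s = 0.072, peak_rate = 1, activated = TRUE)
  b <- data.frame(unit_id = sprintf("b%d", 1:3), odor_id = "o1",
                  concentration = rep(c(0.5, 1), each = 3),
                  peak_time_s = rep(c(0.092, 0.082), each = 3),
                  peak_rate = 1, activated = TRUE)
  cs <- cross_population_synchrony(a, b)
  expect_equal(cs$mean_abs_diff_s, c(0.020, 0.010))  # -10 ms per doubling
  expect_error(cross_population_synchrony(a[0, ], b), "both populations")
})

test_that("peak stats are rate-scale invariant and time equivariant", {
  time <- seq(0.0005, 0.2995, by = 0.001)
  rates <- array(0, c(1, 1, length(time)))
  rates[1, 1, ] <- bump(time, 0.080)
  sdf <- make_sdf(rates, "o1", 1)
  pk1 <- peak_stats(sdf)
  sdf$rate <- sdf$rate * 13
  pk2 <- peak_stats(sdf)
  expect_equal(pk1$peak_time_s, pk2$peak_time_s)
  expect_equal(pk2$peak_rate, 13 * pk1$peak_rate)
  # translate in time
  shift <- 30  # bins
  sdf$rate[1, 1, ] <- c(rep(0, shift),
                        sdf$rate[1, 1, seq_len(length(time) - shift)])
  pk3 <- peak_stats(sdf)
  expect_equal(pk3$peak_time_s, pk1$peak_time_s + shift * 0.001,
               tolerance = 1e-9)
})

test_that("latency shift per doubling is recovered from peak regressions", {
  cfg <- generator_config(n_units = c(pyramidal = 15),
                          n_odors = 2, concentrations = c(0.25, 0.5, 1),
                          trials_per_condition = 25, response_prob = 1,
                          amplitude_mean = 30, amplitude_sd = 0,
                          latency_mean = c(pyramidal = 0.078),
                          latency_sd = 0.010,
                          latency_shift_per_doubling = c(pyramidal = -0.010),
                          rate_gain_per_doubling = c(pyramidal = 1.1))
  out <- aligned_session(cfg, seed = 23)
  sdf <- spike_density(out$raster, out$trials)
  pk <- peak_stats(sdf)
  est <- latency_shift_estimate(pk)
  expect_lt(abs(est$mean_shift - (-0.010)), 0.003)
})
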