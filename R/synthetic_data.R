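#' Configuration for the synthetic recording-session generator
#'
#' Builds the parameter set that drives [simulate_respiration()] and
#' [simulate_session()]. The defaults emulate the structure of an awake
#' head-fixed odor-exposure experiment: 11 odors at four relative
#' concentrations (0.25, 0.33, 0.50, 1.00), 25 repetitions per condition,
#' ~300-ms respiration cycles, 1-s odor pulses triggered at the exhalation
#' phase, and early (< 100 ms post-inhalation) Gaussian response bumps whose
#' amplitude and latency follow log-linear (per-doubling) concentration laws
#' that differ between unit classes.
#'
#' Concentration laws are anchored at the highest concentration
#' \eqn{c_{max}}: `latency(c) = latency_mean + latency_shift_per_doubling *
#' log2(c / c_max)` and `amplitude(c) = amplitude *
#' rate_gain_per_doubling ^ log2(c / c_max)`, so `latency_mean` is the class
#' latency at full concentration and a negative shift makes responses earlier
#' as concentration increases. Across-cell latency dispersion at
#' concentration `c` is `latency_sd * latency_sd_shrink_per_doubling ^
#' log2(c / c_max)`; a shrink factor below 1 makes the population fire more
#' synchronously at higher concentrations.
#'
#' @param n_units named integer vector of unit counts per class. Recognised
#'   classes are `"fan"` (latency-invariant), `"pyramidal"` (latency shifts
#'   earlier with concentration), `"ca1"` (latency shifts, no rate gain) and
#'   `"untuned"` (never odor-responsive).
#' @param n_odors number of odors.
#' @param concentrations strictly increasing relative concentrations.
#' @param trials_per_condition repetitions of each odor x concentration.
#' @param n_blank_trials number of blank (no odor) trials.
#' @param respiration_period_mean,respiration_period_sd mean and SD (s) of
#'   the per-cycle respiration period.
#' @param sampling_rate respiration sampling rate (Hz, >= 100).
#' @param pressure_noise_sd SD of additive Gaussian noise on the pressure
#'   signal, as a fraction of the unit cycle amplitude.
#' @param odor_duration odor pulse length (s).
#' @param inter_trial_interval trial spacing (s).
#' @param baseline_rate baseline firing rate (spikes/s).
#' @param response_prob probability that a unit responds to a given odor
#'   (classes other than `"untuned"`).
#' @param amplitude_mean,amplitude_sd gamma-distributed response-bump
#'   amplitude (spikes/s) at the highest concentration; `amplitude_sd = 0`
#'   gives a point mass.
#' @param latency_mean named vector, class response latency (s) at the
#'   highest concentration.
#' @param latency_sd across-cell latency SD (s) at the highest concentration.
#' @param latency_shift_per_doubling named vector (s per doubling of
#'   concentration; negative = earlier at higher concentration).
#' @param latency_sd_shrink_per_doubling multiplicative change of the
#'   latency SD per concentration doubling (< 1 shrinks).
#' @param rate_gain_per_doubling named vector, multiplicative amplitude gain
#'   per concentration doubling (1 = concentration-invariant rate).
#' @param response_width Gaussian response-bump SD (s).
#' @param epoch_pre,epoch_post spike-generation epoch around each odor onset
#'   (s before / after); spikes are simulated only within these epochs.
#' @param seed default integer seed for the generator.
#' @return an object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_units = c(fan = 40, pyramidal = 40, ca1 = 0,
                                         untuned = 20),
                             n_odors = 11,
                             concentrations = c(0.25, 0.33, 0.50, 1.00),
                             trials_per_condition = 25,
                             n_blank_trials = trials_per_condition,
                             respiration_period_mean = 0.30,
                             respiration_period_sd = 0.02,
                             sampling_rate = 1000,
                             pressure_noise_sd = 0.01,
                             odor_duration = 1.0,
                             inter_trial_interval = 4.0,
                             baseline_rate = 3,
                             response_prob = 0.14,
                             amplitude_mean = 15,
                             amplitude_sd = 5,
                             latency_mean = c(fan = 0.072, pyramidal = 0.078,
                                              ca1 = 0.106, untuned = 0.075),
                             latency_sd = 0.015,
                             latency_shift_per_doubling =
                               c(fan = 0, pyramidal = -0.010,
                                 ca1 = -0.010, untuned = 0),
                             latency_sd_shrink_per_doubling = 0.8,
                             rate_gain_per_doubling =
                               c(fan = 1.1, pyramidal = 1.1,
                                 ca1 = 1.0, untuned = 1.0),
                             response_width = 0.025,
                             epoch_pre = 0.5,
                             epoch_post = 1.2,
                             seed = 1) {
  cfg <- list(n_units = n_units, n_odors = n_odors,
              concentrations = concentrations,
              trials_per_condition = trials_per_condition,
              n_blank_trials = n_blank_trials,
              respiration_period_mean = respiration_period_mean,
              respiration_period_sd = respiration_period_sd,
              sampling_rate = sampling_rate,
              pressure_noise_sd = pressure_noise_sd,
              odor_duration = odor_duration,
              inter_trial_interval = inter_trial_interval,
              baseline_rate = baseline_rate,
              response_prob = response_prob,
              amplitude_mean = amplitude_mean,
              amplitude_sd = amplitude_sd,
              latency_mean = latency_mean,
              latency_sd = latency_sd,
              latency_shift_per_doubling = latency_shift_per_doubling,
              latency_sd_shrink_per_doubling = latency_sd_shrink_per_doubling,
              rate_gain_per_doubling = rate_gain_per_doubling,
              response_width = response_width,
              epoch_pre = epoch_pre, epoch_post = epoch_post,
              seed = seed)
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  classes <- names(cfg$n_units)
  if (is.null(classes) || any(classes == ""))
    stop("n_units must be a named vector of per-class unit counts")
  if (any(cfg$n_units < 0) || sum(cfg$n_units) < 1)
    stop("at least one unit is required")
  if (cfg$n_odors < 1) stop("n_odors must be >= 1")
  if (any(diff(cfg$concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  if (any(cfg$concentrations <= 0)) stop("concentrations must be positive")
  if (cfg$trials_per_condition < 2) stop("trials_per_condition must be >= 2")
  if (cfg$respiration_period_mean <= 0)
    stop("respiration period must be positive")
  if (cfg$respiration_period_sd < 0) stop("period SD must be >= 0")
  if (cfg$sampling_rate < 100) stop("sampling rate must be >= 100 Hz")
  if (cfg$baseline_rate < 0 || cfg$amplitude_mean < 0)
    stop("rates must be >= 0")
  if (cfg$response_prob < 0 || cfg$response_prob > 1)
    stop("response_prob must be in [0, 1]")
  if (cfg$response_width <= 0) stop("response_width must be positive")
  for (nm in c("latency_mean", "latency_shift_per_doubling",
               "rate_gain_per_doubling")) {
    if (!all(classes %in% names(cfg[[nm]])))
      stop(nm, " must name every class in n_units")
  }
  if (any(cfg$latency_mean < 0)) stop("latencies must be >= 0")
  structure(cfg, class = "generator_config")
}

#' Simulate a quasi-periodic respiration pressure trace
#'
#' Generates a pressure signal built from concatenated sinusoidal cycles
#' whose periods are drawn around `respiration_period_mean` (Gaussian,
#' truncated at one third of the mean). Each cycle starts at an inhalation
#' onset: the pressure is `-sin(2*pi*u)` with `u` the fraction through the
#' cycle, so the signal deflects downward during inhalation (first half
#' cycle) and upward during exhalation (second half). The true inhalation
#' onsets (cycle starts) are returned alongside the trace.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param duration trace length in seconds; by default long enough for the
#'   configured trial count.
#' @return object of class `respiration_trace`: list with `time` (s),
#'   `pressure`, `fs`, and `onsets` (true inhalation-onset times, s).
#' @export
simulate_respiration <- function(config, seed = config$seed,
                                 duration = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(duration)) {
    n_trials <- config$n_odors * length(config$concentrations) *
      config$trials_per_condition + config$n_blank_trials
    duration <- (n_trials + 1) * config$inter_trial_interval + 2
  }
  if (duration <= 0) stop("duration must be positive")
  with_seed(sub_seed(seed, 101L), {
    mu <- config$respiration_period_mean
    n_cycles <- ceiling(duration / (mu * 0.5)) + 3L
    periods <- pmax(stats::rnorm(n_cycles, mu, config$respiration_period_sd),
                    mu / 3)
    starts <- c(0, cumsum(periods))[seq_len(n_cycles)]
    time <- seq(0, duration, by = 1 / config$sampling_rate)
    ci <- findInterval(time, starts)
    u <- (time - starts[ci]) / periods[ci]
    pressure <- -sin(2 * pi * u)
    if (config$pressure_noise_sd > 0)
      pressure <- pressure +
        stats::rnorm(length(pressure), 0, config$pressure_noise_sd)
    structure(list(time = time, pressure = pressure,
                   fs = config$sampling_rate,
                   onsets = starts[starts <= duration],
                   periods = periods[starts <= duration]),
              class = "respiration_trace")
  })
}

## Internal: draw the per-unit/odor ground-truth response structure.
draw_ground_truth <- function(config, units) {
  odors <- sprintf("odor%02d", seq_len(config$n_odors))
  gt <- expand.grid(unit_id = units$unit_id, odor_id = odors,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gt$class <- units$class[match(gt$unit_id, units$unit_id)]
  p <- ifelse(gt$class == "untuned", 0, config$response_prob)
  gt$responsive <- stats::runif(nrow(gt)) < p
  if (config$amplitude_sd > 0) {
    shape <- (config$amplitude_mean / config$amplitude_sd)^2
    rate <- config$amplitude_mean / config$amplitude_sd^2
    amp <- stats::rgamma(nrow(gt), shape = shape, rate = rate)
  } else {
    amp <- rep(config$amplitude_mean, nrow(gt))
  }
  gt$amplitude <- ifelse(gt$responsive, amp, 0)
  gt$latency_z <- stats::rnorm(nrow(gt))
  gt
}

## Internal: class-specific latency at concentration c for ground-truth rows.
gt_latency <- function(config, gt, conc) {
  cmax <- max(config$concentrations)
  d <- log2(conc / cmax)
  lat <- config$latency_mean[gt$class] +
    config$latency_shift_per_doubling[gt$class] * d +
    gt$latency_z * config$latency_sd *
      config$latency_sd_shrink_per_doubling^d
  pmax(lat, 0)
}

gt_amplitude <- function(config, gt, conc) {
  cmax <- max(config$concentrations)
  gt$amplitude * config$rate_gain_per_doubling[gt$class]^log2(conc / cmax)
}

#' Simulate a full synthetic recording session
#'
#' Generates a respiration trace, a randomized trial sequence (every odor at
#' every concentration, `trials_per_condition` times, plus blank trials),
#' and spike trains for every unit as inhomogeneous Poisson processes
#' sampled by thinning. Odor onsets are locked to the exhalation phase
#' (placed at the midpoint of the ascending half-cycle), and each responsive
#' unit-odor pair adds a Gaussian rate bump of class-specific latency and
#' concentration-scaled amplitude on top of the baseline rate, centred on
#' the first inhalation of odor. All draws are recorded in the returned
#' ground truth.
#'
#' Spikes are generated within an epoch `[odor_on - epoch_pre, odor_on +
#' epoch_post)` around each trial, which covers the aligned analysis windows;
#' inter-epoch quiescence is not simulated.
#'
#' @param config a [generator_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @return object of class `sniff_session`: list with `trace`
#'   (`respiration_trace`), `trials` (trial table), `spikes` (data frame
#'   `unit_id`, `spike_time_s`, sorted by time), `units` (unit metadata) and
#'   `ground_truth` (list of `responses`, `latencies`, `trials`).
#' @export
simulate_session <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  if (sum(config$n_units) < 1) stop("at least one unit is required")
  n_cond_trials <- config$n_odors * length(config$concentrations) *
    config$trials_per_condition
  if (n_cond_trials < 1) stop("at least one trial is required")

  units <- data.frame(
    unit_id = sprintf("u%03d", seq_len(sum(config$n_units))),
    class = rep(names(config$n_units), config$n_units),
    stringsAsFactors = FALSE)

  ## trial sequence ---------------------------------------------------
  conds <- expand.grid(odor_id = sprintf("odor%02d", seq_len(config$n_odors)),
                       concentration = config$concentrations,
                       rep = seq_len(config$trials_per_condition),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  conds <- conds[, c("odor_id", "concentration")]
  if (config$n_blank_trials > 0) {
    conds <- rbind(conds, data.frame(
      odor_id = rep("blank", config$n_blank_trials),
      concentration = NA_real_, stringsAsFactors = FALSE))
  }
  ord <- with_seed(sub_seed(seed, 202L), sample.int(nrow(conds)))
  conds <- conds[ord, , drop = FALSE]
  n_trials <- nrow(conds)

  trace <- simulate_respiration(config, seed = seed)

  ## odor onsets at exhalation midpoints; t0 = next inhalation onset --
  onsets <- trace$onsets
  periods <- trace$periods
  exh_mid <- onsets + 0.75 * periods
  scheduled <- seq_len(n_trials) * config$inter_trial_interval
  cyc <- findInterval(scheduled, exh_mid) + 1L
  cyc <- pmin(cyc, length(exh_mid) - 1L)
  odor_on <- exh_mid[cyc]
  t0_true <- onsets[cyc + 1L]

  trials <- data.frame(
    trial_id = sprintf("t%04d", seq_len(n_trials)),
    odor_id = conds$odor_id,
    concentration = conds$concentration,
    odor_on_s = odor_on,
    led = FALSE,
    stringsAsFactors = FALSE)

  gt <- with_seed(sub_seed(seed, 303L), draw_ground_truth(config, units))

  ## per-condition latency/amplitude lookup tables --------------------
  lat_tab <- do.call(rbind, lapply(config$concentrations, function(cc) {
    data.frame(unit_id = gt$unit_id, odor_id = gt$odor_id,
               concentration = cc,
               latency_s = gt_latency(config, gt, cc),
               amplitude = ifelse(gt$responsive,
                                  gt_amplitude(config, gt, cc), 0),
               stringsAsFactors = FALSE)
  }))

  ## spike generation by thinning, vectorized across trials per unit --
  epoch_lo <- odor_on - config$epoch_pre
  epoch_hi <- odor_on + config$epoch_post
  epoch_len <- epoch_hi - epoch_lo
  w <- config$response_width
  key <- function(u, o, cc) paste(u, o, cc, sep = "\r")
  lat_map <- lat_tab$latency_s
  amp_map <- lat_tab$amplitude
  names(lat_map) <- names(amp_map) <- key(lat_tab$unit_id, lat_tab$odor_id,
                                          lat_tab$concentration)
  is_odor <- trials$odor_id != "blank"

  spikes <- with_seed(sub_seed(seed, 404L), {
    out <- vector("list", nrow(units))
    for (ui in seq_len(nrow(units))) {
      uid <- units$unit_id[ui]
      kk <- key(uid, trials$odor_id, trials$concentration)
      amp <- ifelse(is_odor, unname(amp_map[kk]), 0)
      amp[is.na(amp)] <- 0
      lat <- ifelse(is_odor, unname(lat_map[kk]), 0)
      centre <- t0_true + lat
      rmax <- config$baseline_rate + amp
      n_cand <- stats::rpois(n_trials, rmax * epoch_len)
      if (sum(n_cand) == 0) { out[[ui]] <- numeric(0); next }
      idx <- rep.int(seq_len(n_trials), n_cand)
      tt <- epoch_lo[idx] + stats::runif(length(idx)) * epoch_len[idx]
      rate <- config$baseline_rate +
        amp[idx] * exp(-((tt - centre[idx])^2) / (2 * w^2))
      keep <- stats::runif(length(idx)) * rmax[idx] < rate
      out[[ui]] <- sort(tt[keep])
    }
    data.frame(
      unit_id = rep(units$unit_id, lengths(out)),
      spike_time_s = unlist(out, use.names = FALSE),
      stringsAsFactors = FALSE)
  })
  spikes <- spikes[order(spikes$spike_time_s, spikes$unit_id), , drop = FALSE]
  rownames(spikes) <- NULL

  gt_trials <- trials
  gt_trials$t0_true_s <- t0_true
  structure(list(
    trace = trace, trials = trials, spikes = spikes, units = units,
    ground_truth = list(
      responses = gt[, c("unit_id", "odor_id", "class", "responsive",
                         "amplitude")],
      latencies = lat_tab,
      trials = gt_trials),
    config = config, seed = seed), class = "sniff_session")
}

#' Configuration for the synthetic 2AFC behavioral generator
#'
#' @param n_trials trials per session.
#' @param accuracy programmed probability of a correct choice on control
#'   (LED off) trials, in `[0, 1]`.
#' @param led_accuracy programmed accuracy on LED (optogenetic silencing)
#'   trials; 0.5 models performance at chance.
#' @param led_fraction fraction of trials with the LED on.
#' @param respond_prob probability that a trial receives any lick response.
#' @param decision_latency earliest possible first-lick time relative to the
#'   first odor inhalation (s).
#' @param lick_jitter_sd SD of the (folded-normal) lick-latency jitter added
#'   to `decision_latency` (s).
#' @param seed default integer seed.
#' @return object of class `behavior_config`.
#' @export
behavior_config <- function(n_trials = 300, accuracy = 0.8,
                            led_accuracy = 0.5, led_fraction = 0.25,
                            respond_prob = 0.95, decision_latency = 0.2,
                            lick_jitter_sd = 0.025, seed = 1) {
  if (accuracy < 0 || accuracy > 1 || led_accuracy < 0 || led_accuracy > 1)
    stop("accuracy must be in [0, 1]")
  if (led_fraction < 0 || led_fraction > 1)
    stop("led_fraction must be in [0, 1]")
  if (n_trials < 1) stop("n_trials must be >= 1")
  if (decision_latency < 0 || lick_jitter_sd < 0)
    stop("latency parameters must be >= 0")
  structure(list(n_trials = n_trials, accuracy = accuracy,
                 led_accuracy = led_accuracy, led_fraction = led_fraction,
                 respond_prob = respond_prob,
                 decision_latency = decision_latency,
                 lick_jitter_sd = lick_jitter_sd, seed = seed),
            class = "behavior_config")
}

#' Simulate a two-alternative forced-choice behavioral session
#'
#' Each trial presents stimulus class `"A"` or `"B"` (equiprobable). LED
#' trials are drawn at `led_fraction`; correctness is Bernoulli at the
#' programmed accuracy for the trial's LED state. Responded trials receive a
#' first-lick time `decision_latency + |N(0, lick_jitter_sd)|` relative to
#' the first odor inhalation, and the chosen side equals the stimulus side
#' on correct trials.
#'
#' @param config a [behavior_config()].
#' @param seed integer seed (defaults to `config$seed`).
#' @param session_id label stored with the session.
#' @return object of class `behavior_session`: data frame with `trial_id`,
#'   `stim`, `led`, `responded`, `lick_time_s`, `choice`, `correct`.
#' @export
simulate_behavior <- function(config, seed = config$seed,
                              session_id = "session1") {
  stopifnot(inherits(config, "behavior_config"))
  with_seed(sub_seed(seed, 505L), {
    n <- config$n_trials
    stim <- sample(c("A", "B"), n, replace = TRUE)
    led <- stats::runif(n) < config$led_fraction
    responded <- stats::runif(n) < config$respond_prob
    acc <- ifelse(led, config$led_accuracy, config$accuracy)
    correct <- stats::runif(n) < acc
    choice <- ifelse(correct, stim, ifelse(stim == "A", "B", "A"))
    lick <- config$decision_latency +
      abs(stats::rnorm(n, 0, config$lick_jitter_sd))
    out <- data.frame(
      trial_id = sprintf("t%04d", seq_len(n)),
      stim = stim, led = led, responded = responded,
      lick_time_s = ifelse(responded, lick, NA_real_),
      choice = ifelse(responded, choice, NA_character_),
      correct = ifelse(responded, correct, NA),
      stringsAsFactors = FALSE)
    structure(out, class = c("behavior_session", "data.frame"),
              session_id = session_id)
  })
}
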