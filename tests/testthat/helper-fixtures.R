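# Shared fixture builders. Everything is generated in code; no files.

tiny_config <- function(...) {
  generator_config(n_units = c(fan = 6, pyramidal = 6, untuned = 3),
                   n_odors = 3, concentrations = c(0.25, 0.5, 1),
                   trials_per_condition = 6, seed = 42, ...)
}

# Session with distinct (disjoint-ish) odor ensembles: high response
# probability but only a few odors, strong amplitudes, no amplitude spread.
separable_config <- function(...) {
  generator_config(n_units = c(fan = 12, pyramidal = 12, untuned = 0),
                   n_odors = 3, concentrations = c(0.5, 1),
                   trials_per_condition = 10, response_prob = 0.4,
                   amplitude_mean = 30, amplitude_sd = 0,
                   seed = 42, ...)
}

aligned_session <- function(cfg, seed = cfg$seed) {
  sess <- simulate_session(cfg, seed = seed)
  trials <- align_trials(sess$trials, detect_inhalation_onsets(sess$trace),
                         cfg$odor_duration)
  raster <- build_raster(sess$spikes, trials)
  list(session = sess, trials = trials, raster = raster)
}

# Independent hand evaluation of the lifetime-sparseness formula, written
# as an explicit loop so it shares no code with the implementation.
sparseness_oracle <- function(r) {
  r2 <- numeric(length(r))
  for (i in seq_along(r)) r2[i] <- max(r[i], 0)
  n <- length(r2)
  num <- 0
  for (x in r2) num <- num + x / n
  den <- 0
  for (x in r2) den <- den + x * x / n
  if (den == 0) return(NA_real_)
  (1 - num * num / den) / (1 - 1 / n)
}
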