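## Gaussian smoothing of a uniformly sampled signal, edge-normalized so the
## kernel mass lost at the borders does not bias the local mean.
gauss_smooth <- function(x, sd_samples) {
  if (sd_samples <= 0) return(x)
  half <- max(1L, ceiling(4 * sd_samples))
  k <- stats::dnorm(seq(-half, half), 0, sd_samples)
  k <- k / sum(k)
  n <- length(x)
  pad <- rep(0, half)
  sm <- as.numeric(stats::filter(c(pad, x, pad), k, sides = 2))
  norm <- as.numeric(stats::filter(c(pad, rep(1, n), pad), k, sides = 2))
  sm[(half + 1):(half + n)] / norm[(half + 1):(half + n)]
}

#' Detect inhalation onsets from a respiration pressure trace
#'
#' Inhalation onsets are taken as descending zero crossings of the smoothed,
#' mean-subtracted pressure signal, using a Schmitt trigger: a crossing is
#' accepted only after the signal has exceeded `+hysteresis` and is
#' triggered when it falls below `-hysteresis`, which suppresses noise
#' re-crossings. Crossing times are linearly interpolated between samples.
#'
#' @param trace a `respiration_trace` (or list with `time` and `pressure`).
#' @param smoothing_ms SD of the Gaussian pre-smoothing kernel (ms).
#' @param hysteresis crossing threshold in signal units; defaults to 10% of
#'   the SD of the smoothed signal.
#' @return sorted, strictly increasing onset times (s). A constant trace
#'   yields an empty vector.
#' @export
detect_inhalation_onsets <- function(trace, smoothing_ms = 5,
                                     hysteresis = NULL) {
  time <- trace$time
  x <- trace$pressure
  if (length(x) < 3L) return(numeric(0))
  if (!all(is.finite(x))) stop("pressure trace must be finite")
  fs <- 1 / stats::median(diff(time))
  x <- gauss_smooth(x, smoothing_ms / 1000 * fs)
  x <- x - mean(x)
  h <- hysteresis %||% (0.1 * stats::sd(x))
  if (stats::sd(x) == 0) return(numeric(0))

  state <- rep(NA_integer_, length(x))
  state[x > h] <- 1L
  state[x < -h] <- -1L
  known <- which(!is.na(state))
  if (length(known) < 2L) return(numeric(0))
  ## forward-fill the Schmitt state between threshold excursions
  runs <- rle(state[known])
  vals <- runs$values
  ends <- cumsum(runs$lengths)
  starts_i <- c(1L, utils::head(ends, -1L) + 1L)
  trig <- which(vals == -1L & c(NA, utils::head(vals, -1L)) == 1L)
  if (length(trig) == 0L) return(numeric(0))
  trig_idx <- known[starts_i[trig]]  # first sample below -h after being high

  pos_idx <- which(x >= 0)
  ki <- findInterval(trig_idx - 1L, pos_idx)
  k <- ifelse(ki >= 1L, pos_idx[pmax(ki, 1L)], NA_integer_)
  k[!is.na(k) & k >= length(x)] <- NA_integer_
  ## linear interpolation of the zero crossing in [k, k+1]
  onsets <- time[k] + (time[k + 1L] - time[k]) * x[k] / (x[k] - x[k + 1L])
  onsets <- onsets[is.finite(onsets)]
  sort(unique(onsets))
}

#' Align trials to the first inhalation of odor
#'
#' For each trial, `t0_s` is the earliest detected inhalation onset at or
#' after odor onset and within the odor pulse; trials without such an onset
#' are flagged invalid rather than dropped.
#'
#' @param trials trial table with `odor_on_s`.
#' @param onsets sorted inhalation-onset times (s).
#' @param odor_duration odor pulse length (s); the onset must fall in
#'   `[odor_on_s, odor_on_s + odor_duration)`.
#' @return the trial table with columns `t0_s` and `valid` added.
#' @export
align_trials <- function(trials, onsets, odor_duration = 1.0) {
  stopifnot(is.data.frame(trials), "odor_on_s" %in% names(trials))
  if (is.unsorted(onsets)) stop("onsets must be sorted")
  if (anyDuplicated(trials$trial_id)) stop("trial_id must be unique")
  if (length(onsets) == 0L) {
    trials$t0_s <- NA_real_
    trials$valid <- FALSE
    return(trials)
  }
  ## first onset >= odor_on (at-or-after rule)
  i <- findInterval(trials$odor_on_s, onsets, left.open = TRUE) + 1L
  t0 <- ifelse(i <= length(onsets), onsets[pmin(i, length(onsets))], NA_real_)
  ok <- !is.na(t0) & t0 < trials$odor_on_s + odor_duration
  trials$t0_s <- ifelse(ok, t0, NA_real_)
  trials$valid <- ok
  trials
}

#' Build an aligned spike raster
#'
#' Re-references spike times to each valid trial's `t0_s` and keeps spikes
#' in the half-open analysis window `[w_lo, w_hi)`. Spike counts within the
#' window are conserved relative to the source stream; invalid trials are
#' skipped with a message.
#'
#' @param spikes data frame with `unit_id`, `spike_time_s`.
#' @param trials aligned trial table (from [align_trials()] or the
#'   generator's ground truth) with `t0_s` and `valid`.
#' @param window half-open analysis window `c(w_lo, w_hi)` (s, relative to
#'   `t0_s`).
#' @param units optional character vector of unit ids defining the full unit
#'   set (defaults to the units present in `spikes`).
#' @return object of class `aligned_raster`: data frame `unit_id`,
#'   `trial_id`, `rel_time_s` with attributes `window`, `units`,
#'   `trial_ids`.
#' @export
build_raster <- function(spikes, trials, window = c(-0.1, 0.3),
                         units = NULL) {
  check_window(window)
  stopifnot(all(c("unit_id", "spike_time_s") %in% names(spikes)))
  if (!all(c("t0_s", "valid") %in% names(trials)))
    stop("trials must be aligned first (columns t0_s, valid)")
  n_bad <- sum(!trials$valid)
  if (n_bad > 0)
    message("build_raster: skipping ", n_bad, " invalid trial(s)")
  trials <- trials[trials$valid, , drop = FALSE]
  ord <- order(spikes$spike_time_s)
  st <- spikes$spike_time_s[ord]
  su <- spikes$unit_id[ord]
  parts <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    lo <- trials$t0_s[i] + window[1]
    hi <- trials$t0_s[i] + window[2]
    a <- findInterval(lo, st, left.open = TRUE) + 1L
    b <- findInterval(hi, st, left.open = TRUE)  # last spike < hi
    if (b < a) next
    parts[[i]] <- data.frame(unit_id = su[a:b],
                             trial_id = trials$trial_id[i],
                             rel_time_s = st[a:b] - trials$t0_s[i],
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, parts)
  if (is.null(out))
    out <- data.frame(unit_id = character(0), trial_id = character(0),
                      rel_time_s = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("aligned_raster", "data.frame"),
            window = window,
            units = units %||% sort(unique(spikes$unit_id)),
            trial_ids = trials$trial_id)
}

#' Identify optogenetically tagged (phototagged) units
#'
#' A unit is tagged when (i) its firing rate in the `[0, window_ms)` ms
#' window after LED pulse onset significantly exceeds the rate in the
#' `[-baseline_ms, 0)` ms pre-pulse window (paired one-sided t-test across
#' pulses, `p < alpha`), and (ii) its first-spike latency is consistent
#' across pulses (SD `<= jitter_max_ms`).
#'
#' @param spikes data frame with `unit_id`, `spike_time_s`.
#' @param pulse_times LED pulse onset times (s); at least 20 pulses.
#' @param window_ms post-pulse response window (ms).
#' @param alpha significance level for the rate increase.
#' @param jitter_max_ms maximum allowed first-spike latency SD (ms).
#' @param baseline_ms pre-pulse baseline window length (ms).
#' @param units optional full unit-id set.
#' @return data frame per unit: `unit_id`, `tagged`, `p_value`,
#'   `latency_sd_ms`, `n_response_pulses`.
#' @export
identify_phototagged <- function(spikes, pulse_times, window_ms = 5,
                                 alpha = 0.05, jitter_max_ms = 2,
                                 baseline_ms = 10, units = NULL) {
  if (length(pulse_times) == 0L) stop("no LED pulses supplied")
  if (length(pulse_times) < 20L) stop("at least 20 pulses are required")
  pulse_times <- sort(pulse_times)
  w <- window_ms / 1000
  b <- baseline_ms / 1000
  units <- units %||% sort(unique(spikes$unit_id))
  by_unit <- split(spikes$spike_time_s, spikes$unit_id)
  res <- lapply(units, function(uid) {
    st <- sort(by_unit[[uid]] %||% numeric(0))
    post <- findInterval(pulse_times + w, st, left.open = TRUE) -
      findInterval(pulse_times, st, left.open = TRUE)
    pre <- findInterval(pulse_times, st, left.open = TRUE) -
      findInterval(pulse_times - b, st, left.open = TRUE)
    tt <- paired_t_greater(post / w, pre / b)
    ## first-spike latency per pulse (pulses with a response only)
    first_i <- findInterval(pulse_times, st, left.open = TRUE) + 1L
    has <- post > 0 & first_i <= length(st)
    lat_ms <- (st[first_i[has]] - pulse_times[has]) * 1000
    lat_sd <- if (length(lat_ms) >= 2L) stats::sd(lat_ms) else NA_real_
    data.frame(unit_id = uid,
               tagged = isTRUE(!is.na(tt$p) && tt$p < alpha &&
                                 !is.na(lat_sd) && lat_sd <= jitter_max_ms),
               p_value = tt$p, latency_sd_ms = lat_sd,
               n_response_pulses = sum(has), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
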