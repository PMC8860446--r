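#' Percent correct choices in a 2AFC session
#'
#' Fraction of correct choices among responded trials, optionally
#' stratified by LED (optogenetic silencing) state.
#'
#' @param session a `behavior_session` (or data frame with `responded`,
#'   `correct`, `led`).
#' @param stratify_by_led split by LED state (default `TRUE`).
#' @return data frame `led`, `n_responded`, `n_correct`, `percent`; strata
#'   with no responded trials get `NA` with a warning.
#' @export
percent_correct <- function(session, stratify_by_led = TRUE) {
  groups <- if (stratify_by_led) split(session, session$led)
    else list(all = session)
  out <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    resp <- d[which(d$responded), , drop = FALSE]
    data.frame(led = g, n_responded = nrow(resp),
               n_correct = sum(resp$correct),
               percent = if (nrow(resp) > 0)
                 100 * mean(resp$correct) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n_responded == 0))
    warning("stratum without responded trials: percent undefined")
  rownames(out) <- NULL
  out
}

#' Signal-detection discriminability from hit and false-alarm rates
#'
#' `d' = z(HR) - z(FAR)` with `z` the standard-normal quantile. Rates of 0
#' or 1 give infinite values; use the log-linear corrected counts (as in
#' [dprime_timecourse()]) when working from counts.
#'
#' @param hit_rate,fa_rate rates in `[0, 1]`.
#' @return d-prime.
#' @export
dprime <- function(hit_rate, fa_rate) {
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Cumulative-response d-prime time course
#'
#' At each time `t`, a trial counts as a response toward side A if its
#' first lick occurred at or before `t` and chose A. The hit rate is the
#' cumulative probability of an A response among class-A trials, the
#' false-alarm rate the same among class-B trials; unresponded-by-t trials
#' stay in the denominators (cumulative response probabilities). Rates are
#' log-linear corrected (`(k + 0.5) / (n + 1)`) so d' stays finite at 0/1
#' rates.
#'
#' @param session a `behavior_session` with both stimulus classes.
#' @param step time-grid step (s), default 0.025.
#' @param t_max last grid time (s), default 2 (the response window).
#' @return data frame of class `dprime_curve`: `t_s`, `hr`, `far`,
#'   `dprime`, `n_hit`, `n_fa`.
#' @export
dprime_timecourse <- function(session, step = 0.025, t_max = 2) {
  if (step <= 0) stop("step must be positive")
  if (length(unique(session$stim)) < 2L)
    stop("both stimulus classes must be present")
  tt <- seq(0, t_max, by = step)
  is_a <- session$stim == "A"
  n_a <- sum(is_a)
  n_b <- sum(!is_a)
  resp_a_time <- ifelse(!is.na(session$choice) & session$choice == "A",
                        session$lick_time_s, Inf)
  n_hit <- vapply(tt, function(t) sum(resp_a_time[is_a] <= t), numeric(1))
  n_fa <- vapply(tt, function(t) sum(resp_a_time[!is_a] <= t), numeric(1))
  hr <- (n_hit + 0.5) / (n_a + 1)
  far <- (n_fa + 0.5) / (n_b + 1)
  out <- data.frame(t_s = tt, hr = hr, far = far,
                    dprime = dprime(hr, far), n_hit = n_hit, n_fa = n_fa)
  class(out) <- c("dprime_curve", "data.frame")
  attr(out, "step") <- step
  out
}

## d-prime curve after shuffling stimulus labels within a session.
shuffled_dprime <- function(session, step, t_max, n_shuffle, seed) {
  with_seed(seed, {
    curves <- vapply(seq_len(n_shuffle), function(i) {
      s <- session
      s$stim <- sample(s$stim)
      dprime_timecourse(s, step, t_max)$dprime
    }, numeric(length(seq(0, t_max, by = step))))
    rowMeans(curves)
  })
}

#' Onset of significant behavioral discriminability
#'
#' Estimates the earliest time at which the cumulative-response d' across
#' sessions differs from a session-wise label-shuffled null (paired t-test
#' at each step, `p < alpha`) for at least `k_consec` consecutive steps.
#'
#' @param sessions list of at least 3 `behavior_session` objects.
#' @param step,t_max time grid passed to [dprime_timecourse()].
#' @param alpha significance level.
#' @param k_consec required run of consecutive significant steps
#'   (default 3, suppressing isolated significant bins).
#' @param n_shuffle label shuffles per session for the null curve.
#' @param seed integer seed for the shuffles.
#' @return list with `onset_s` (`NA` if never significant), `t_s`, `p`,
#'   `dprime_mean`, `null_mean`.
#' @export
dprime_onset <- function(sessions, step = 0.025, t_max = 2, alpha = 0.05,
                         k_consec = 3, n_shuffle = 100, seed = 1) {
  if (length(sessions) < 3L) stop("at least 3 sessions are required")
  obs <- vapply(sessions, function(s) dprime_timecourse(s, step, t_max)$dprime,
                numeric(length(seq(0, t_max, by = step))))
  null <- vapply(seq_along(sessions), function(i) {
    shuffled_dprime(sessions[[i]], step, t_max, n_shuffle,
                    sub_seed(seed, 1000L + i))
  }, numeric(nrow(obs)))
  tt <- seq(0, t_max, by = step)
  p <- vapply(seq_along(tt), function(i) {
    d <- obs[i, ] - null[i, ]
    if (stats::sd(d) == 0) return(if (mean(d) == 0) 1 else 0)
    stats::t.test(d)$p.value
  }, numeric(1))
  sig <- p < alpha
  onset <- NA_real_
  run <- rle(sig)
  ends <- cumsum(run$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  hit <- which(run$values & run$lengths >= k_consec)
  if (length(hit) > 0) onset <- tt[starts[hit[1]]]
  list(onset_s = onset, t_s = tt, p = p,
       dprime_mean = rowMeans(obs), null_mean = rowMeans(null))
}

#' Paired LED on/off comparison of session performance
#'
#' Paired t-test of percent correct across sessions with and without
#' optogenetic silencing, with per-state mean and SEM.
#'
#' @param pc data frame with `session_id`, `led` (logical or
#'   `"TRUE"`/`"FALSE"`), `percent` (one row per session x state);
#'   sessions lacking either state are dropped with a message.
#' @return list with `mean_off`, `sem_off`, `mean_on`, `sem_on`, `t`, `df`,
#'   `p`, `n_sessions`.
#' @export
led_comparison <- function(pc) {
  pc$led <- as.logical(pc$led)
  wide <- merge(pc[!pc$led, c("session_id", "percent")],
                pc[pc$led, c("session_id", "percent")],
                by = "session_id", suffixes = c("_off", "_on"))
  dropped <- length(unique(pc$session_id)) - nrow(wide)
  if (dropped > 0)
    message("led_comparison: dropping ", dropped,
            " session(s) without both LED states")
  if (nrow(wide) < 3L) stop("at least 3 paired sessions are required")
  d <- wide$percent_off - wide$percent_on
  if (stats::sd(d) == 0) {
    tt <- list(statistic = if (mean(d) == 0) 0 else Inf * sign(mean(d)),
               parameter = nrow(wide) - 1,
               p.value = if (mean(d) == 0) 1 else 0)
  } else {
    tt <- stats::t.test(wide$percent_off, wide$percent_on, paired = TRUE)
  }
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(mean_off = mean(wide$percent_off), sem_off = sem(wide$percent_off),
       mean_on = mean(wide$percent_on), sem_on = sem(wide$percent_on),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, n_sessions = nrow(wide))
}
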