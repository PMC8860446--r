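## Time grid of bin centres for an analysis window.
sdf_grid <- function(window, step) {
  n <- round((window[2] - window[1]) / step)
  window[1] + (seq_len(n) - 0.5) * step
}

## Gaussian kernel matrix K[i, j] = dnorm(t_i - t_j, 0, sigma): a spike in
## bin j contributes a unit-area Gaussian evaluated at bin centre i. Kernel
## mass truncated at the window edges is not renormalized.
sdf_kernel_matrix <- function(time, sigma) {
  outer(time, time, function(a, b) stats::dnorm(a - b, 0, sigma))
}

#' Spike-density function for a single spike train
#'
#' Convolves a spike train with a unit-area Gaussian kernel
#' (default sigma 10 ms) on a uniform grid of bin centres. The time
#' integral of the result equals the in-window spike count up to the kernel
#' mass truncated at the window edges.
#'
#' @param times spike times (s, relative).
#' @param window half-open analysis window `c(lo, hi)` (s).
#' @param sigma Gaussian kernel SD (s), > 0.
#' @param grid_step grid resolution (s).
#' @return list with `time` (bin centres) and `rate` (spikes/s).
#' @export
sdf_single <- function(times, window, sigma = 0.010, grid_step = 0.001) {
  if (sigma <= 0) stop("sigma must be positive")
  check_window(window)
  time <- sdf_grid(window, grid_step)
  times <- times[times >= window[1] & times < window[2]]
  if (length(times) == 0L) return(list(time = time,
                                       rate = numeric(length(time))))
  rate <- rowSums(vapply(times, function(s) stats::dnorm(time - s, 0, sigma),
                         numeric(length(time))))
  list(time = time, rate = rate)
}

#' Trial-averaged spike-density functions per unit and condition
#'
#' Computes Gaussian-kernel spike-density functions (SDFs) from an aligned
#' raster, averaged over the trials of each condition (odor x
#' concentration, including blank). Each spike contributes a unit-area
#' Gaussian; rates are in spikes/s.
#'
#' @param raster an [build_raster()] `aligned_raster`.
#' @param trials trial table with `trial_id`, `odor_id`, `concentration`
#'   (only trials present in the raster are used).
#' @param sigma kernel SD (s), default 0.010.
#' @param grid_step grid resolution (s), default 0.001.
#' @return object of class `spike_density`: list with `time`, `rate`
#'   (array `unit x condition x time`), `units`, `conditions` (data frame
#'   with `cond_id`, `odor_id`, `concentration`, `n_trials`), `sigma`,
#'   `grid_step`, `window`.
#' @export
spike_density <- function(raster, trials, sigma = 0.010, grid_step = 0.001) {
  if (sigma <= 0) stop("sigma must be positive")
  window <- attr(raster, "window")
  check_window(window)
  units <- attr(raster, "units")
  trial_ids <- attr(raster, "trial_ids")
  trials <- trials[trials$trial_id %in% trial_ids, , drop = FALSE]
  cond_key <- paste(trials$odor_id, trials$concentration)
  conds <- unique(data.frame(odor_id = trials$odor_id,
                             concentration = trials$concentration,
                             key = cond_key, stringsAsFactors = FALSE))
  conds <- conds[order(conds$odor_id, conds$concentration), , drop = FALSE]
  conds$cond_id <- seq_len(nrow(conds))
  conds$n_trials <- as.vector(table(cond_key)[conds$key])

  time <- sdf_grid(window, grid_step)
  n_bins <- length(time)
  u_i <- match(raster$unit_id, units)
  c_i <- conds$cond_id[match(cond_key[match(raster$trial_id,
                                            trials$trial_id)], conds$key)]
  b_i <- pmin(pmax(floor((raster$rel_time_s - window[1]) / grid_step) + 1L,
                   1L), n_bins)
  keep <- !is.na(u_i) & !is.na(c_i)
  dims <- c(length(units), nrow(conds), n_bins)
  lin <- (u_i[keep] - 1L) + dims[1] * (c_i[keep] - 1L) +
    dims[1] * dims[2] * (b_i[keep] - 1L) + 1L
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)

  K <- sdf_kernel_matrix(time, sigma)
  flat <- matrix(counts, nrow = dims[1] * dims[2], ncol = n_bins)
  rate <- flat %*% K
  rate <- sweep(array(rate, dim = dims), 2, conds$n_trials, "/")
  dimnames(rate) <- list(units, conds$key, NULL)
  structure(list(time = time, rate = rate, units = units,
                 conditions = conds[, c("cond_id", "odor_id",
                                        "concentration", "n_trials", "key")],
                 sigma = sigma, grid_step = grid_step, window = window),
            class = "spike_density")
}

#' Per-trial mean firing rate in a fixed window
#'
#' Counts spikes in the half-open window and divides by its length, for
#' every unit x trial combination in the raster (including silent ones).
#'
#' @param raster an `aligned_raster`.
#' @param window half-open window `c(lo, hi)` within the raster window.
#' @return data frame `unit_id`, `trial_id`, `rate` (spikes/s).
#' @export
window_rate <- function(raster, window) {
  check_window(window)
  units <- attr(raster, "units")
  trial_ids <- attr(raster, "trial_ids")
  len <- window[2] - window[1]
  sel <- raster$rel_time_s >= window[1] & raster$rel_time_s < window[2]
  u_i <- match(raster$unit_id[sel], units)
  t_i <- match(raster$trial_id[sel], trial_ids)
  lin <- (u_i - 1L) + length(units) * (t_i - 1L) + 1L
  counts <- tabulate(lin, nbins = length(units) * length(trial_ids))
  data.frame(unit_id = rep(units, times = length(trial_ids)),
             trial_id = rep(trial_ids, each = length(units)),
             rate = counts / len, stringsAsFactors = FALSE)
}

## Rate matrix [trial x unit] for a set of trial ids, from window_rate output.
rate_matrix <- function(wr, units, trial_ids) {
  m <- matrix(wr$rate[order(match(wr$trial_id, trial_ids),
                            match(wr$unit_id, units))],
              nrow = length(trial_ids), ncol = length(units), byrow = TRUE)
  dimnames(m) <- list(trial_ids, units)
  m
}

#' Activated-unit test: odor vs blank windowed rates
#'
#' Paired one-sided t-test (odor > blank) per unit on per-trial windowed
#' firing rates, pairing trials by presentation order. A unit is activated
#' when the mean rate change is positive and `p < alpha`.
#'
#' @param odor_rates,blank_rates numeric matrices `trials x units` (or
#'   vectors for a single unit), rows paired.
#' @param alpha significance level (default 0.05).
#' @return data frame `unit`, `n`, `delta_rate`, `p`, `activated`. With
#'   fewer than 3 trial pairs the test is undefined and flagged `NA`.
#' @export
activated_units <- function(odor_rates, blank_rates, alpha = 0.05) {
  if (is.vector(odor_rates)) odor_rates <- matrix(odor_rates, ncol = 1)
  if (is.vector(blank_rates)) blank_rates <- matrix(blank_rates, ncol = 1)
  n <- min(nrow(odor_rates), nrow(blank_rates))
  if (ncol(odor_rates) != ncol(blank_rates))
    stop("odor and blank matrices must have the same number of units")
  res <- lapply(seq_len(ncol(odor_rates)), function(j) {
    tt <- paired_t_greater(odor_rates[seq_len(n), j],
                           blank_rates[seq_len(n), j])
    data.frame(unit = colnames(odor_rates)[j] %||% as.character(j),
               n = tt$n, delta_rate = tt$delta, p = tt$p,
               activated = if (is.na(tt$p)) NA else tt$p < alpha)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Activation matrix across units, odors and concentrations
#'
#' Runs [activated_units()] for every odor x concentration condition
#' against the blank trials, using per-trial rates in `window`.
#'
#' @param raster an `aligned_raster`.
#' @param trials trial table with `odor_id`, `concentration`.
#' @param window rate window (s), default the early 50-100 ms window.
#' @param alpha significance level.
#' @param blank_label odor id marking blank trials.
#' @return data frame `unit_id`, `odor_id`, `concentration`, `n`,
#'   `delta_rate`, `p`, `activated`.
#' @export
activation_matrix <- function(raster, trials, window = c(0.05, 0.10),
                              alpha = 0.05, blank_label = "blank") {
  trial_ids <- attr(raster, "trial_ids")
  units <- attr(raster, "units")
  trials <- trials[trials$trial_id %in% trial_ids, , drop = FALSE]
  trials <- trials[order(trials$odor_on_s %||% seq_len(nrow(trials))), ,
                   drop = FALSE]
  wr <- window_rate(raster, window)
  rm_all <- rate_matrix(wr, units, trial_ids)
  blank_ids <- trials$trial_id[trials$odor_id == blank_label]
  if (length(blank_ids) == 0L) stop("no blank trials found")
  blank_m <- rm_all[blank_ids, , drop = FALSE]
  conds <- unique(trials[trials$odor_id != blank_label,
                         c("odor_id", "concentration")])
  out <- lapply(seq_len(nrow(conds)), function(i) {
    sel <- trials$odor_id == conds$odor_id[i] &
      (is.na(conds$concentration[i]) |
         (!is.na(trials$concentration) &
            trials$concentration == conds$concentration[i]))
    ids <- trials$trial_id[sel]
    res <- activated_units(rm_all[ids, , drop = FALSE], blank_m, alpha)
    data.frame(unit_id = res$unit, odor_id = conds$odor_id[i],
               concentration = conds$concentration[i],
               n = res$n, delta_rate = res$delta_rate, p = res$p,
               activated = res$activated, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Lifetime sparseness of a unit's odor responses
#'
#' Computes the normalized selectivity statistic
#' \deqn{S = \frac{1 - (\sum_j r_j / N)^2 / (\sum_j r_j^2 / N)}{1 - 1/N}}
#' over a unit's mean firing-rate changes \eqn{r_j} across the \eqn{N}
#' odors, after clipping negative responses to zero. S = 1 for a unit
#' responding to exactly one odor (completely selective) and S = 0 for a
#' uniform response (nonselective).
#'
#' @param r numeric vector of mean rate changes, one per odor (N >= 2).
#' @return S in `[0, 1]`, or `NA` if all clipped responses are zero
#'   (undefined).
#' @export
lifetime_sparseness <- function(r) {
  if (length(r) < 2L) stop("at least two odors are required")
  if (!all(is.finite(r))) stop("responses must be finite")
  r <- pmax(r, 0)
  n <- length(r)
  if (all(r == 0)) return(NA_real_)
  s <- (1 - (sum(r) / n)^2 / (sum(r^2) / n)) / (1 - 1 / n)
  min(max(s, 0), 1)  # clamp floating-point residue to the statistic's range
}

#' Lifetime sparseness table per unit (and concentration)
#'
#' Applies [lifetime_sparseness()] to each unit's vector of mean rate
#' changes across odors, separately per concentration when present.
#'
#' @param act an [activation_matrix()] result.
#' @return data frame `unit_id`, `concentration`, `sparseness`, `n_odors`.
#' @export
sparseness_table <- function(act) {
  key <- paste(act$unit_id, act$concentration)
  parts <- split(act, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    data.frame(unit_id = d$unit_id[1], concentration = d$concentration[1],
               sparseness = if (nrow(d) >= 2)
                 lifetime_sparseness(d$delta_rate) else NA_real_,
               n_odors = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Histogram of responsive-odor counts and per-odor activation percentages
#'
#' @param act an [activation_matrix()] result (filter to one concentration
#'   first if responses per concentration are wanted).
#' @return list with `histogram` (data frame `n_odors`, `n_units`: units
#'   activated by 0..N odors) and `per_odor` (data frame `odor_id`,
#'   `percent` activated units).
#' @export
responsive_count_histogram <- function(act) {
  units <- unique(act$unit_id)
  odors <- unique(act$odor_id)
  ## count odors with any activation per unit
  cnt <- vapply(units, function(u) {
    d <- act[act$unit_id == u, ]
    length(unique(d$odor_id[which(d$activated)]))
  }, integer(1))
  hist <- data.frame(n_odors = 0:length(odors),
                     n_units = tabulate(cnt + 1L,
                                        nbins = length(odors) + 1L))
  per_odor <- do.call(rbind, lapply(odors, function(o) {
    d <- act[act$odor_id == o, ]
    any_act <- tapply(!is.na(d$activated) & d$activated, d$unit_id, any)
    data.frame(odor_id = o, percent = 100 * mean(any_act),
               stringsAsFactors = FALSE)
  }))
  rownames(per_odor) <- NULL
  list(histogram = hist, per_odor = per_odor)
}

#' Cross-validated rank-ordered peak map
#'
#' For each cell-odor pair, computes the trial-averaged SDF separately on
#' odd- and even-indexed trials (by presentation order within the pair),
#' finds the peak time on the odd-trial SDF, and returns the row-normalized
#' even-trial SDF matrix with rows sorted by the odd-trial peak time.
#'
#' @param raster an `aligned_raster`.
#' @param trials trial table with `odor_id` (and optionally
#'   `concentration`, `odor_on_s` for presentation order).
#' @param sigma,grid_step SDF parameters.
#' @param search_window window for peak extraction (s).
#' @param blank_label odor id marking blank trials (excluded).
#' @return list with `matrix` (pairs x time, even trials, row-normalized),
#'   `time`, and `pairs` (data frame `unit_id`, `odor_id`, `odd_peak_s`,
#'   `even_peak_s`, in plotted row order). Pairs with fewer than 2 trials
#'   are excluded.
#' @export
rank_order_crossval <- function(raster, trials, sigma = 0.010,
                                grid_step = 0.001,
                                search_window = c(0, 0.3),
                                blank_label = "blank") {
  trial_ids <- attr(raster, "trial_ids")
  trials <- trials[trials$trial_id %in% trial_ids &
                     trials$odor_id != blank_label, , drop = FALSE]
  if ("odor_on_s" %in% names(trials))
    trials <- trials[order(trials$odor_on_s), , drop = FALSE]
  parity <- stats::ave(seq_len(nrow(trials)), trials$odor_id,
                       FUN = seq_along) %% 2L
  odd_ids <- trials$trial_id[parity == 1L]
  even_ids <- trials$trial_id[parity == 0L]
  subset_raster <- function(ids) {
    r <- raster[raster$trial_id %in% ids, , drop = FALSE]
    structure(r, class = class(raster), window = attr(raster, "window"),
              units = attr(raster, "units"), trial_ids = ids)
  }
  sdf_odd <- spike_density(subset_raster(odd_ids), trials, sigma, grid_step)
  sdf_even <- spike_density(subset_raster(even_ids), trials, sigma, grid_step)
  time <- sdf_odd$time
  in_win <- time >= search_window[1] & time < search_window[2]
  ## pairs = unit x odor, averaged over concentrations within parity
  units <- sdf_odd$units
  odors <- unique(sdf_odd$conditions$odor_id)
  pairs <- expand.grid(unit_id = units, odor_id = odors,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n_pairs <- nrow(pairs)
  mat <- matrix(0, n_pairs, length(time))
  odd_peak <- even_peak <- numeric(n_pairs)
  keep <- rep(TRUE, n_pairs)
  for (i in seq_len(n_pairs)) {
    ui <- match(pairs$unit_id[i], units)
    ci_o <- which(sdf_odd$conditions$odor_id == pairs$odor_id[i])
    ci_e <- which(sdf_even$conditions$odor_id == pairs$odor_id[i])
    if (length(ci_o) == 0L || length(ci_e) == 0L) {  # single-trial pair
      keep[i] <- FALSE
      next
    }
    ro <- colMeans(matrix(sdf_odd$rate[ui, ci_o, ], nrow = length(ci_o)))
    re <- colMeans(matrix(sdf_even$rate[ui, ci_e, ], nrow = length(ci_e)))
    odd_peak[i] <- time[in_win][which.max(ro[in_win])]
    even_peak[i] <- time[in_win][which.max(re[in_win])]
    mx <- max(re)
    mat[i, ] <- if (mx > 0) re / mx else re
  }
  pairs$odd_peak_s <- odd_peak
  pairs$even_peak_s <- even_peak
  pairs <- pairs[keep, , drop = FALSE]
  mat <- mat[keep, , drop = FALSE]
  ord <- order(pairs$odd_peak_s)
  list(matrix = mat[ord, , drop = FALSE], time = time,
       pairs = pairs[ord, , drop = FALSE])
}

#' Early vs late activated-cell fractions
#'
#' Percent of activated cells per odor in an early and a late analysis
#' window (activation tested against blank in each window).
#'
#' @param raster an `aligned_raster`.
#' @param trials trial table.
#' @param early,late half-open windows (s), defaults `[0, 0.100)` and
#'   `[0.200, 0.300)`.
#' @param alpha significance level.
#' @return data frame `phase`, `odor_id`, `percent`.
#' @export
early_late_fractions <- function(raster, trials, early = c(0, 0.100),
                                 late = c(0.200, 0.300), alpha = 0.05) {
  one <- function(win, label) {
    act <- activation_matrix(raster, trials, window = win, alpha = alpha)
    po <- responsive_count_histogram(act)$per_odor
    data.frame(phase = label, odor_id = po$odor_id, percent = po$percent,
               stringsAsFactors = FALSE)
  }
  rbind(one(early, "early"), one(late, "late"))
}
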