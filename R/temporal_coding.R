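#' Peak time and peak rate per cell-odor-concentration
#'
#' Extracts, from trial-averaged spike-density functions, the earliest time
#' of the maximum (deterministic earliest-tie rule) and the maximum rate in
#' the search window for every unit x condition, optionally restricted to
#' significantly activated pairs.
#'
#' @param sdf a [spike_density()] result.
#' @param search_window half-open peak-search window (s), default
#'   `[0, 0.300)`.
#' @param activation optional [activation_matrix()] result used to flag
#'   activated pairs.
#' @param activated_only if `TRUE`, keep only activated pairs.
#' @param blank_label odor id marking blank conditions (excluded).
#' @return data frame of class `peak_stats`: `unit_id`, `odor_id`,
#'   `concentration`, `peak_time_s`, `peak_rate`, `activated`.
#' @export
peak_stats <- function(sdf, search_window = c(0, 0.300), activation = NULL,
                       activated_only = FALSE, blank_label = "blank") {
  check_window(search_window)
  in_win <- sdf$time >= search_window[1] & sdf$time < search_window[2]
  if (!any(in_win)) stop("empty search window")
  tw <- sdf$time[in_win]
  conds <- sdf$conditions
  keep_c <- which(conds$odor_id != blank_label)
  rows <- vector("list", length(sdf$units) * length(keep_c))
  k <- 0L
  for (ui in seq_along(sdf$units)) {
    for (ci in keep_c) {
      r <- sdf$rate[ui, ci, in_win]
      k <- k + 1L
      pk <- which.max(r)  # which.max returns the earliest maximum
      rows[[k]] <- data.frame(
        unit_id = sdf$units[ui], odor_id = conds$odor_id[ci],
        concentration = conds$concentration[ci],
        peak_time_s = tw[pk], peak_rate = r[pk],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(activation)) {
    key <- function(d) paste(d$unit_id, d$odor_id, d$concentration)
    out$activated <- activation$activated[match(key(out), key(activation))]
  } else {
    out$activated <- NA
  }
  if (activated_only) out <- out[which(out$activated), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_stats", "data.frame")
  out
}

#' Spearman trend of peak statistics across concentrations
#'
#' Rank correlation between concentration and peak time (or peak rate)
#' pooled over cell-odor pairs. Concentrations are ranked, so log or raw
#' scaling gives identical results.
#'
#' @param peaks a [peak_stats()] data frame.
#' @param variable `"peak_time"` or `"peak_rate"`.
#' @return object of class `trend_result`: list with `rho`, `p`, `n`.
#'   A constant variable yields `rho = NA` with a warning (undefined, not
#'   silently zero).
#' @export
concentration_trend <- function(peaks,
                                variable = c("peak_time", "peak_rate")) {
  variable <- match.arg(variable)
  v <- switch(variable, peak_time = peaks$peak_time_s,
              peak_rate = peaks$peak_rate)
  ok <- !is.na(v) & !is.na(peaks$concentration)
  v <- v[ok]
  cc <- peaks$concentration[ok]
  if (length(unique(cc)) < 2L) stop("at least two concentrations required")
  if (length(v) < 10L) stop("at least 10 cell-odor pairs required")
  if (stats::sd(v) == 0) {
    warning("constant ", variable, ": trend undefined")
    return(structure(list(rho = NA_real_, p = NA_real_, n = length(v)),
                     class = "trend_result"))
  }
  ct <- suppressWarnings(stats::cor.test(cc, v, method = "spearman",
                                         exact = FALSE))
  structure(list(rho = unname(ct$estimate), p = ct$p.value, n = length(v)),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.4f, p = %.3g, n = %d\n", x$rho, x$p, x$n))
  invisible(x)
}

#' Estimate the latency shift per concentration doubling
#'
#' Regresses peak time on log2(concentration) within each cell-odor pair
#' (requiring at least two concentrations) and summarizes the per-pair
#' slopes. Under the generator's log-linear latency law the mean slope
#' recovers `latency_shift_per_doubling`.
#'
#' @param peaks a [peak_stats()] data frame.
#' @return list with `per_pair` (data frame `unit_id`, `odor_id`,
#'   `slope_s_per_doubling`), `mean_shift`, `se`.
#' @export
latency_shift_estimate <- function(peaks) {
  ok <- !is.na(peaks$peak_time_s) & !is.na(peaks$concentration)
  d <- peaks[ok, , drop = FALSE]
  parts <- split(d, paste(d$unit_id, d$odor_id))
  rows <- lapply(parts, function(p) {
    if (length(unique(p$concentration)) < 2L) return(NULL)
    sl <- stats::coef(stats::lm(peak_time_s ~ log2(concentration),
                                data = p))[2]
    data.frame(unit_id = p$unit_id[1], odor_id = p$odor_id[1],
               slope_s_per_doubling = unname(sl), stringsAsFactors = FALSE)
  })
  per_pair <- do.call(rbind, rows)
  rownames(per_pair) <- NULL
  list(per_pair = per_pair,
       mean_shift = mean(per_pair$slope_s_per_doubling),
       se = stats::sd(per_pair$slope_s_per_doubling) /
         sqrt(nrow(per_pair)))
}

## Mean absolute pairwise difference of a numeric vector.
mean_abs_pairwise <- function(x) {
  if (length(x) < 2L) return(NA_real_)
  mean(abs(outer(x, x, "-"))[lower.tri(diag(length(x)))])
}

#' Mean pairwise peak-time difference (population synchrony)
#'
#' For each concentration and odor, computes the mean absolute peak-time
#' difference over all unordered pairs of responding cells, then averages
#' within odor and across odors (the within-odor form keeps the statistic a
#' synchrony measure rather than an odor-tuning measure). Smaller values
#' mean more synchronized firing.
#'
#' @param peaks a [peak_stats()] data frame; restrict to activated pairs
#'   upstream if desired.
#' @param pool_odors if `TRUE`, pool all pairs across odors instead of
#'   averaging within odor first.
#' @return data frame `concentration`, `mean_abs_diff_s`, `n_pairs`. If no
#'   odor has two responses at a concentration the value is `NA` (flagged
#'   by a warning).
#' @export
pairwise_peak_time_diff <- function(peaks, pool_odors = FALSE) {
  ok <- !is.na(peaks$peak_time_s) & !is.na(peaks$concentration)
  d <- peaks[ok, , drop = FALSE]
  concs <- sort(unique(d$concentration))
  out <- lapply(concs, function(cc) {
    dc <- d[d$concentration == cc, , drop = FALSE]
    if (pool_odors) {
      val <- mean_abs_pairwise(dc$peak_time_s)
      npairs <- choose(nrow(dc), 2)
    } else {
      per_odor <- tapply(dc$peak_time_s, dc$odor_id, mean_abs_pairwise)
      npairs <- sum(vapply(split(dc$peak_time_s, dc$odor_id),
                           function(x) choose(length(x), 2), numeric(1)))
      val <- mean(per_odor, na.rm = TRUE)
      if (all(is.na(per_odor))) val <- NA_real_
    }
    data.frame(concentration = cc, mean_abs_diff_s = val, n_pairs = npairs)
  })
  out <- do.call(rbind, out)
  if (any(is.na(out$mean_abs_diff_s)))
    warning("some concentrations had fewer than 2 responses per odor; NA")
  out
}

#' Between-class peak-time synchrony across concentrations
#'
#' Restricts peak-time pairs to one cell from each of two populations
#' (e.g. phototagged fan vs pyramidal cells) responding to the same odor,
#' and computes the mean absolute peak-time difference per concentration
#' (within odor, averaged across odors).
#'
#' @param peaks_a,peaks_b [peak_stats()] data frames for the two classes.
#' @return data frame `concentration`, `mean_abs_diff_s`, `n_pairs`.
#' @export
cross_population_synchrony <- function(peaks_a, peaks_b) {
  ok_a <- !is.na(peaks_a$peak_time_s) & !is.na(peaks_a$concentration)
  ok_b <- !is.na(peaks_b$peak_time_s) & !is.na(peaks_b$concentration)
  a <- peaks_a[ok_a, , drop = FALSE]
  b <- peaks_b[ok_b, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both populations must contribute responses")
  concs <- sort(intersect(unique(a$concentration), unique(b$concentration)))
  out <- lapply(concs, function(cc) {
    ac <- a[a$concentration == cc, ]
    bc <- b[b$concentration == cc, ]
    odors <- intersect(unique(ac$odor_id), unique(bc$odor_id))
    per_odor <- vapply(odors, function(o) {
      mean(abs(outer(ac$peak_time_s[ac$odor_id == o],
                     bc$peak_time_s[bc$odor_id == o], "-")))
    }, numeric(1))
    npairs <- sum(vapply(odors, function(o) {
      sum(ac$odor_id == o) * sum(bc$odor_id == o)
    }, numeric(1)))
    data.frame(concentration = cc,
               mean_abs_diff_s = if (length(per_odor)) mean(per_odor)
                 else NA_real_,
               n_pairs = npairs)
  })
  do.call(rbind, out)
}
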