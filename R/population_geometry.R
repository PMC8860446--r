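#' Assemble a pseudopopulation response tensor
#'
#' Concatenates units across recordings and matches trials within each
#' condition by seed-controlled random pairing (identity pairing for a
#' single recording), producing a dense `units x condition x trial x
#' time-bin` array of firing rates (spikes/s). Recordings missing any
#' shared condition are excluded with a message.
#'
#' @param recordings list of recordings, each a list with elements `raster`
#'   (an `aligned_raster`) and `trials` (trial table with `odor_id`,
#'   `concentration`), and optionally `units` (metadata data frame).
#' @param window half-open time window (s) for the tensor (within each
#'   raster's window).
#' @param bin bin width (s); a single bin spanning the whole window gives a
#'   windowed-scalar tensor suitable for fixed-window decoding.
#' @param seed integer seed controlling trial pairing.
#' @return object of class `response_tensor`: list with `rate` (4-d array),
#'   `units` (data frame `unit_id`, `recording`, optionally `class`),
#'   `conditions` (data frame `odor_id`, `concentration`, `key`), `time`
#'   (bin centres), `window`, `bin`.
#' @export
build_pseudopopulation <- function(recordings, window = c(-0.1, 0.3),
                                   bin = 0.001, seed = 1) {
  check_window(window)
  if (length(recordings) == 0L) stop("no recordings supplied")
  cond_key <- function(tr) paste(tr$odor_id, tr$concentration)
  cond_of <- function(rec) {
    tr <- rec$trials[rec$trials$trial_id %in% attr(rec$raster, "trial_ids"), ]
    unique(cond_key(tr))
  }
  keys <- Reduce(intersect, lapply(recordings, cond_of))
  keep <- vapply(recordings, function(r) all(keys %in% cond_of(r)),
                 logical(1))
  if (!all(keep)) {
    message("build_pseudopopulation: excluding ", sum(!keep),
            " recording(s) missing shared conditions")
    recordings <- recordings[keep]
  }
  ref <- recordings[[1]]$trials
  ref <- unique(data.frame(odor_id = ref$odor_id,
                           concentration = ref$concentration,
                           key = cond_key(ref), stringsAsFactors = FALSE))
  conds <- ref[ref$key %in% keys, , drop = FALSE]
  conds <- conds[order(conds$odor_id, conds$concentration), , drop = FALSE]
  rownames(conds) <- NULL

  ## trials per condition = minimum across recordings
  n_trials <- min(vapply(recordings, function(rec) {
    tr <- rec$trials[rec$trials$trial_id %in% attr(rec$raster, "trial_ids"), ]
    min(table(cond_key(tr))[conds$key])
  }, numeric(1)))
  if (n_trials < 1) stop("no complete trials across recordings")

  edges <- seq(window[1], window[2], by = bin)
  n_bins <- length(edges) - 1L
  time <- (edges[-1] + edges[-length(edges)]) / 2
  single <- length(recordings) == 1L

  per_rec <- lapply(seq_along(recordings), function(ri) {
    rec <- recordings[[ri]]
    raster <- rec$raster
    units <- attr(raster, "units")
    tr <- rec$trials[rec$trials$trial_id %in% attr(raster, "trial_ids"), ]
    tr$key <- cond_key(tr)
    ## seed-controlled trial pairing per condition
    sel <- with_seed(sub_seed(seed, 600L + ri), {
      do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
        ids <- tr$trial_id[tr$key == conds$key[ci]]
        ids <- if (single) ids[seq_len(n_trials)] else
          sample(ids)[seq_len(n_trials)]
        data.frame(trial_id = ids, cond = ci, rank = seq_len(n_trials),
                   stringsAsFactors = FALSE)
      }))
    })
    r <- raster[raster$trial_id %in% sel$trial_id, , drop = FALSE]
    u_i <- match(r$unit_id, units)
    m <- match(r$trial_id, sel$trial_id)
    c_i <- sel$cond[m]
    k_i <- sel$rank[m]
    b_i <- floor((r$rel_time_s - window[1]) / bin) + 1L
    ok <- !is.na(u_i) & b_i >= 1L & b_i <= n_bins
    dims <- c(length(units), nrow(conds), n_trials, n_bins)
    lin <- (u_i[ok] - 1L) + dims[1] * (c_i[ok] - 1L) +
      dims[1] * dims[2] * (k_i[ok] - 1L) +
      dims[1] * dims[2] * dims[3] * (b_i[ok] - 1L) + 1L
    rate <- array(tabulate(lin, nbins = prod(dims)), dim = dims) / bin
    meta <- data.frame(unit_id = units, recording = ri,
                       stringsAsFactors = FALSE)
    if (!is.null(rec$units) && "class" %in% names(rec$units))
      meta$class <- rec$units$class[match(units, rec$units$unit_id)]
    list(rate = rate, meta = meta)
  })
  rate <- do.call(abind_units, lapply(per_rec, `[[`, "rate"))
  units <- do.call(rbind, lapply(per_rec, `[[`, "meta"))
  structure(list(rate = rate, units = units, conditions = conds,
                 time = time, window = window, bin = bin),
            class = "response_tensor")
}

## Bind 4-d arrays along the unit (first) dimension.
abind_units <- function(...) {
  arrs <- list(...)
  if (length(arrs) == 1L) return(arrs[[1]])
  d <- dim(arrs[[1]])
  out <- array(0, dim = c(sum(vapply(arrs, function(a) dim(a)[1],
                                     numeric(1))), d[2], d[3], d[4]))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' PCA trajectories of population activity
#'
#' Fits PCA over the unit dimension of a response tensor (observations are
#' time bins per condition, either trial-averaged or per trial; units are
#' mean-centred, not variance-scaled) and returns the per-condition mean
#' trajectory of the first `K` components.
#'
#' @param tensor a [build_pseudopopulation()] `response_tensor`.
#' @param K number of components to keep (default 3; must not exceed the
#'   unit count).
#' @param mode `"trial_average"` (default) fits on per-condition
#'   trial-averaged rate vectors; `"per_trial"` fits on single-trial
#'   vectors and averages scores afterwards.
#' @return object of class `pca_trajectory`: list with `scores` (array
#'   `condition x time x K`), `explained` (variance fractions, all
#'   components), `loadings` (`unit x K`, orthonormal), `time`,
#'   `conditions`.
#' @export
pca_trajectories <- function(tensor, K = 3,
                             mode = c("trial_average", "per_trial")) {
  mode <- match.arg(mode)
  d <- dim(tensor$rate)
  if (d[1] < K) stop("fewer units than requested components")
  avg <- apply(tensor$rate, c(1, 2, 4), mean)  # unit x cond x bin
  if (mode == "trial_average") {
    X <- t(matrix(avg, nrow = d[1]))  # (cond*bin) x unit
  } else {
    X <- t(matrix(aperm(tensor$rate, c(1, 2, 3, 4)), nrow = d[1]))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  ## project the trial-averaged trajectories
  Xavg <- t(matrix(avg, nrow = d[1]))
  sc <- sweep(Xavg, 2, pc$center) %*% pc$rotation[, seq_len(K), drop = FALSE]
  scores <- array(sc, dim = c(d[2], d[4], K))
  structure(list(scores = scores, explained = expl,
                 loadings = pc$rotation[, seq_len(K), drop = FALSE],
                 time = tensor$time, conditions = tensor$conditions),
            class = "pca_trajectory")
}

#' Condition pairs for distance analyses
#'
#' @param conditions a tensor/trajectory `conditions` data frame.
#' @param type `"identity"`: same concentration, different odors;
#'   `"intensity"`: same odor, different concentrations; `"all"`: every
#'   unordered pair.
#' @return two-column integer matrix of condition row indices.
#' @export
condition_pairs <- function(conditions, type = c("all", "identity",
                                                 "intensity")) {
  type <- match.arg(type)
  n <- nrow(conditions)
  pr <- t(utils::combn(n, 2))
  if (type == "identity") {
    same_c <- (is.na(conditions$concentration[pr[, 1]]) &
                 is.na(conditions$concentration[pr[, 2]])) |
      (conditions$concentration[pr[, 1]] ==
         conditions$concentration[pr[, 2]])
    keep <- same_c %in% TRUE &
      conditions$odor_id[pr[, 1]] != conditions$odor_id[pr[, 2]]
    pr <- pr[keep, , drop = FALSE]
  } else if (type == "intensity") {
    keep <- conditions$odor_id[pr[, 1]] == conditions$odor_id[pr[, 2]] &
      !is.na(conditions$concentration[pr[, 1]]) &
      !is.na(conditions$concentration[pr[, 2]]) &
      conditions$concentration[pr[, 1]] !=
        conditions$concentration[pr[, 2]]
    pr <- pr[keep %in% TRUE, , drop = FALSE]
  }
  pr
}

#' Euclidean-distance time course between condition trajectories
#'
#' At each time bin, the Euclidean distance in K-dimensional principal
#' component score space is computed for every requested condition pair and
#' averaged (unweighted) over pairs.
#'
#' @param trajectory a [pca_trajectories()] result.
#' @param pairs two-column matrix of condition indices (e.g. from
#'   [condition_pairs()]); must be non-empty.
#' @return data frame `t_s`, `distance`; the per-pair distance matrix is
#'   attached as attribute `per_pair`.
#' @export
euclidean_distance_timecourse <- function(trajectory,
                                          pairs = condition_pairs(
                                            trajectory$conditions)) {
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0L) stop("empty condition pair set")
  sc <- trajectory$scores
  per_pair <- vapply(seq_len(nrow(pairs)), function(i) {
    dif <- sc[pairs[i, 1], , , drop = FALSE] -
      sc[pairs[i, 2], , , drop = FALSE]
    sqrt(apply(dif^2, 2, sum))
  }, numeric(dim(sc)[2]))
  per_pair <- matrix(per_pair, nrow = dim(sc)[2])
  out <- data.frame(t_s = trajectory$time,
                    distance = rowMeans(per_pair))
  attr(out, "per_pair") <- per_pair
  out
}
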