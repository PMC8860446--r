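## Windowed feature matrix from a response tensor: mean rate per unit in
## [w0, w1) per (condition, trial) sample. Returns list(X, cond_index).
tensor_features <- function(tensor, window) {
  check_window(window)
  sel <- tensor$time >= window[1] & tensor$time < window[2]
  if (!any(sel)) stop("window contains no tensor bins")
  d <- dim(tensor$rate)
  sub <- tensor$rate[, , , sel, drop = FALSE]
  feat <- apply(sub, c(1, 2, 3), mean)       # unit x cond x trial
  X <- t(matrix(feat, nrow = d[1]))          # (cond*trial... by column) x unit
  cond_index <- rep(seq_len(d[2]), times = d[3])
  list(X = X, cond_index = cond_index, n_trials = d[3])
}

## Resolve decoding labels: a condition-table column name or an explicit
## per-condition vector. Conditions with NA labels (e.g. blank) are dropped.
resolve_labels <- function(tensor, labels) {
  if (is.character(labels) && length(labels) == 1L &&
      labels %in% c("odor", "identity")) {
    lab <- tensor$conditions$odor_id
    lab[lab == "blank"] <- NA
  } else if (is.character(labels) && length(labels) == 1L &&
             labels %in% c("concentration", "intensity")) {
    lab <- as.character(tensor$conditions$concentration)
  } else {
    if (length(labels) != nrow(tensor$conditions))
      stop("labels must name a condition variable or give one label per ",
           "condition")
    lab <- as.character(labels)
  }
  lab
}

## Core repeated stratified-holdout linear-SVM decoder.
decode_core <- function(X, y, feature_mode, n_repeats, holdout, seed,
                        cost = 1) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("at least two classes are required")
  if (any(table(y) < 2L)) stop("every class needs at least 2 trials")
  acc <- with_seed(sub_seed(seed, 700L), {
    vapply(seq_len(n_repeats), function(r) {
      ## equal trials per class by subsampling, then stratified holdout
      n_per <- min(table(y))
      idx <- unlist(lapply(levels(y), function(l) {
        sample(which(y == l))[seq_len(n_per)]
      }), use.names = FALSE)
      n_test <- max(1L, round(holdout * n_per))
      test <- unlist(lapply(seq_len(nlevels(y)), function(k) {
        idx[(k - 1L) * n_per + seq_len(n_test)]
      }), use.names = FALSE)
      train <- setdiff(idx, test)
      Xtr <- X[train, , drop = FALSE]
      Xte <- X[test, , drop = FALSE]
      if (feature_mode == "binary") {
        thr <- colMeans(Xtr)  # threshold fitted on the training split only
        Xtr <- 1 * sweep(Xtr, 2, thr, ">")
        Xte <- 1 * sweep(Xte, 2, thr, ">")
      }
      fit <- e1071::svm(Xtr, y[train], kernel = "linear", cost = cost,
                        scale = FALSE)
      mean(predict(fit, Xte) == y[test])
    }, numeric(1))
  })
  acc
}

#' Fixed-window linear decoding of condition labels
#'
#' Decodes class labels from pseudopopulation activity using a linear
#' support-vector machine in a one-vs-one coding scheme with repeated
#' stratified 20% holdout validation. Features are per-unit mean firing
#' rates in the window (`"rate"`) or 0/1 activation indicators thresholded
#' at the unit's training-split mean (`"binary"`, no test-set leakage).
#' Class imbalance is removed by seeded subsampling to equal trial counts.
#'
#' @param tensor a `response_tensor`.
#' @param labels `"identity"` (odor), `"intensity"` (concentration), or an
#'   explicit per-condition label vector (NA drops a condition).
#' @param window decoding window (s), default the early 50-100 ms window.
#' @param feature_mode `"rate"` or `"binary"`.
#' @param n_repeats holdout repetitions (default 50).
#' @param holdout test fraction (default 0.2).
#' @param seed integer seed.
#' @param cost SVM regularization constant (default 1).
#' @return object of class `decoding_result`: list with `accuracy` (per
#'   repeat), `mean`, `sd`, `chance`, `n_classes`, `window`,
#'   `feature_mode`.
#' @export
decode_fixed <- function(tensor, labels = "identity",
                         window = c(0.05, 0.10),
                         feature_mode = c("rate", "binary"),
                         n_repeats = 50, holdout = 0.2, seed = 1,
                         cost = 1) {
  feature_mode <- match.arg(feature_mode)
  lab <- resolve_labels(tensor, labels)
  ft <- tensor_features(tensor, window)
  y <- lab[ft$cond_index]
  keep <- !is.na(y)
  acc <- decode_core(ft$X[keep, , drop = FALSE], y[keep], feature_mode,
                     n_repeats, holdout, seed, cost)
  k <- length(unique(y[keep]))
  structure(list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 chance = 1 / k, n_classes = k, window = window,
                 feature_mode = feature_mode),
            class = "decoding_result")
}

#' Sliding-window linear decoding
#'
#' Runs [decode_fixed()] at window positions advancing by `step` across the
#' tensor's time range (window starts `w_lo, w_lo + step, ...`; the number
#' of positions is `floor((T - window) / step) + 1`).
#'
#' @inheritParams decode_fixed
#' @param window window length (s), default 0.050.
#' @param step window step (s), default 0.005.
#' @return data frame `window_start`, `window_center`, `accuracy`, `sd`,
#'   `chance`.
#' @export
decode_sliding <- function(tensor, labels = "identity", window = 0.050,
                           step = 0.005, feature_mode = c("rate", "binary"),
                           n_repeats = 50, holdout = 0.2, seed = 1,
                           cost = 1) {
  feature_mode <- match.arg(feature_mode)
  lo <- tensor$window[1]
  hi <- tensor$window[2]
  n_pos <- floor((hi - lo - window) / step + 1e-9) + 1L
  starts <- lo + step * (seq_len(n_pos) - 1L)
  rows <- lapply(starts, function(s) {
    r <- decode_fixed(tensor, labels, window = c(s, s + window),
                      feature_mode = feature_mode, n_repeats = n_repeats,
                      holdout = holdout, seed = seed, cost = cost)
    data.frame(window_start = s, window_center = s + window / 2,
               accuracy = r$mean, sd = r$sd, chance = r$chance)
  })
  do.call(rbind, rows)
}

#' Decoding accuracy as a function of ensemble size
#'
#' For each requested ensemble size, draws `n_draws` random unit subsets
#' (seed-controlled) and runs [decode_fixed()] on each.
#'
#' @inheritParams decode_fixed
#' @param sizes ensemble sizes (each >= 1 and <= unit count).
#' @param n_draws random subsets per size.
#' @return data frame `size`, `draw`, `accuracy`.
#' @export
ensemble_size_curve <- function(tensor, labels = "identity", sizes,
                                n_draws = 5, window = c(0.05, 0.10),
                                feature_mode = c("rate", "binary"),
                                n_repeats = 10, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  n_units <- dim(tensor$rate)[1]
  if (any(sizes < 1L)) stop("ensemble sizes must be >= 1")
  if (any(sizes > n_units)) stop("ensemble size exceeds unit count")
  rows <- list()
  for (si in seq_along(sizes)) {
    subsets <- with_seed(sub_seed(seed, 800L + si), {
      lapply(seq_len(n_draws), function(d) sample(n_units, sizes[si]))
    })
    for (d in seq_len(n_draws)) {
      sub <- tensor
      sub$rate <- tensor$rate[subsets[[d]], , , , drop = FALSE]
      sub$units <- tensor$units[subsets[[d]], , drop = FALSE]
      r <- decode_fixed(sub, labels, window = window,
                        feature_mode = feature_mode, n_repeats = n_repeats,
                        seed = sub_seed(seed, 900L + si * 37L + d))
      rows[[length(rows) + 1L]] <-
        data.frame(size = sizes[si], draw = d, accuracy = r$mean)
    }
  }
  do.call(rbind, rows)
}

#' Identity decoding within each concentration
#'
#' Slices the tensor by concentration and decodes odor identity within each
#' stratum with [decode_fixed()]. Strata with fewer than two odors are
#' skipped with a message.
#'
#' @inheritParams decode_fixed
#' @return data frame `concentration`, `accuracy`, `sd`, `chance`.
#' @export
decode_identity_per_concentration <- function(tensor,
                                              window = c(0.05, 0.10),
                                              feature_mode = c("rate",
                                                               "binary"),
                                              n_repeats = 50, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  concs <- sort(unique(stats::na.omit(tensor$conditions$concentration)))
  rows <- lapply(concs, function(cc) {
    sel <- which(!is.na(tensor$conditions$concentration) &
                   tensor$conditions$concentration == cc &
                   tensor$conditions$odor_id != "blank")
    if (length(unique(tensor$conditions$odor_id[sel])) < 2L) {
      message("skipping concentration ", cc, ": fewer than two odors")
      return(NULL)
    }
    sub <- slice_tensor(tensor, sel)
    r <- decode_fixed(sub, "identity", window = window,
                      feature_mode = feature_mode, n_repeats = n_repeats,
                      seed = seed)
    data.frame(concentration = cc, accuracy = r$mean, sd = r$sd,
               chance = r$chance)
  })
  do.call(rbind, rows)
}

#' Intensity decoding within each odor
#'
#' @inheritParams decode_fixed
#' @return data frame `odor_id`, `accuracy`, `sd`, `chance`.
#' @export
decode_intensity_per_odor <- function(tensor, window = c(0.05, 0.10),
                                      feature_mode = c("rate", "binary"),
                                      n_repeats = 50, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  odors <- setdiff(unique(tensor$conditions$odor_id), "blank")
  rows <- lapply(odors, function(o) {
    sel <- which(tensor$conditions$odor_id == o &
                   !is.na(tensor$conditions$concentration))
    if (length(unique(tensor$conditions$concentration[sel])) < 2L) {
      message("skipping odor ", o, ": fewer than two concentrations")
      return(NULL)
    }
    sub <- slice_tensor(tensor, sel)
    r <- decode_fixed(sub, "intensity", window = window,
                      feature_mode = feature_mode, n_repeats = n_repeats,
                      seed = seed)
    data.frame(odor_id = o, accuracy = r$mean, sd = r$sd, chance = r$chance,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

## Subset a response tensor to a set of condition rows.
slice_tensor <- function(tensor, cond_idx) {
  tensor$rate <- tensor$rate[, cond_idx, , , drop = FALSE]
  tensor$conditions <- tensor$conditions[cond_idx, , drop = FALSE]
  tensor
}
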