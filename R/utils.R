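#' @keywords internal
"_PACKAGE"

## Derive a deterministic sub-stream seed from the global seed. Keeps all
## derived seeds below 2^31 - 1 so set.seed() accepts them as integers.
sub_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) %% 1000003L) * 2011L + offset) %% 2147483629L
}

## Evaluate `expr` under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

check_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2L || !all(is.finite(window)))
    stop(what, " must be a numeric vector c(lo, hi)", call. = FALSE)
  if (window[2] <= window[1])
    stop(what, " must satisfy lo < hi", call. = FALSE)
  invisible(window)
}

## One-sided (greater) paired t-test that tolerates zero-variance
## differences: a constant positive shift is maximally significant, a
## constant zero/negative shift is not. Returns list(p, delta, n).
paired_t_greater <- function(x, y) {
  d <- x - y
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3L) return(list(p = NA_real_, delta = mean(d), n = n))
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    p <- if (m > 0) 0 else 1
  } else {
    p <- stats::pt(m / (s / sqrt(n)), df = n - 1L, lower.tail = FALSE)
  }
  list(p = p, delta = m, n = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
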