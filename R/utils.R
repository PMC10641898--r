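# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Centered moving average with shrinking windows at the edges (no NA padding).
moving_average <- function(x, w) {
  w <- as.integer(w)
  if (w <= 1L) return(x)
  n <- length(x)
  i <- seq_len(n)
  lo <- pmax(1L, i - (w %/% 2L))
  hi <- pmin(n, i + ((w - 1L) %/% 2L))
  cs <- c(0, cumsum(x))
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Runs of TRUE in a logical vector as (start, end) inclusive 1-based indices.
logical_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

# Percentile with linear interpolation between order statistics (R type 7).
pct <- function(x, p) stats::quantile(x, p, names = FALSE, type = 7)

# Circular overlap sums for every lag: out[m + 1] = sum_t a[t] * b[t - m],
# indices modulo length. Equivalent to scoring every circular forward shift of
# `b` against `a`; computed exactly via FFT cross-correlation.
circular_overlap <- function(a, b = NULL, fa = NULL, fb = NULL) {
  if (is.null(fa)) fa <- stats::fft(a)
  if (is.null(fb)) fb <- stats::fft(b)
  n <- length(fa)
  Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / n
}

# Integer-valued circular overlap of two 0/1 vectors.
circular_overlap_counts <- function(a, b = NULL, fa = NULL, fb = NULL) {
  round(circular_overlap(a, b, fa, fb))
}
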