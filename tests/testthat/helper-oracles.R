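# Independent oracles and small fixture builders used across tests.
# These deliberately avoid the package's own computational paths.

# Brute-force all-pairs shortest paths (Floyd-Warshall) on a dense length
# matrix; Inf where no edge.
fw_shortest_paths <- function(D) {
  n <- nrow(D)
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Closeness centrality evaluated directly from the formula on a dense
# weight matrix (NA = no edge), natural log distances.
brute_closeness <- function(W) {
  n <- nrow(W)
  D <- matrix(Inf, n, n)
  D[!is.na(W)] <- log(1 / W[!is.na(W)])
  D <- fw_shortest_paths(D)
  vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    A <- sum(is.finite(d))
    if (A == 0) return(0)
    (A / (n - 1))^2 / sum(d[is.finite(d)])
  }, numeric(1))
}

# Direct circular forward shift of a vector by m samples.
rot <- function(x, m) x[((seq_along(x) - m - 1) %% length(x)) + 1]

# Random sparse event train: Poisson onsets with fixed-length rising phases.
random_train <- function(n, rate_per_min, fs = 20, rise_n = 10) {
  p <- rate_per_min / 60 / fs
  ons <- which(stats::runif(n) < p)
  ons <- ons[ons + rise_n <= n]
  x <- integer(n)
  for (o in ons) x[o:(o + rise_n)] <- 1L
  x
}

# A bout segmentation built directly from planted run intervals.
seg_from_bouts <- function(n, bouts, fs = 20) {
  v <- numeric(n)
  for (k in seq_len(nrow(bouts))) v[bouts$start[k]:bouts$end[k]] <- 15
  segment_bouts(speed_trace(v, fs = fs))
}

# A clean synthetic trace with planted events (linear rise, exp decay).
planted_trace <- function(n, onsets, amp = 0.5, rise_n = 10, decay_n = 20,
                          noise_sd = 0, fs = 20) {
  kern <- c(0, seq_len(rise_n) / rise_n, exp(-seq_len(6 * decay_n) / decay_n))
  x <- numeric(n)
  for (o in onsets) {
    idx <- o + seq_along(kern) - 1L
    keep <- idx <= n
    x[idx[keep]] <- x[idx[keep]] + amp * kern[keep]
  }
  x + stats::rnorm(n, 0, noise_sd)
}
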