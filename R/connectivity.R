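#' Pixel-to-micrometer conversion for the imaging field of view
#'
#' @param px Distance in pixels.
#' @param um_per_px Field-of-view scale; default 1.343 mm over 1,024 pixels.
#' @return Distance in micrometers.
#' @export
px_to_um <- function(px, um_per_px = 1343 / 1024) px * um_per_px

#' Is a neuron pair far enough apart for correlation analysis?
#'
#' Pairs closer than 20 pixels (26.2 um at the default field-of-view scale)
#' are excluded to avoid fluorescence cross-contamination; "at least" 20
#' pixels is eligible.
#'
#' @param c_i,c_j Centroids as `c(x, y)` in pixels.
#' @param min_dist_px Minimum centroid distance in pixels (default 20).
#' @return Logical.
#' @export
pair_eligible <- function(c_i, c_j, min_dist_px = 20) {
  sqrt(sum((as.numeric(c_i) - as.numeric(c_j))^2)) >= min_dist_px
}

#' Concatenate the samples of a train belonging to one behavioral scope
#'
#' @param x A per-sample vector (binarized train or trace).
#' @param seg A [segment_bouts()] result.
#' @param scope `"session"` (identity), `"rest"` or `"run"`.
#' @return The concatenated sub-vector, in temporal order.
#' @export
state_concatenate <- function(x, seg, scope = c("session", "rest", "run")) {
  scope <- match.arg(scope)
  if (scope == "session") return(x)
  idx <- state_indices(seg, scope)
  if (!length(idx)) stop("state_concatenate: no samples in scope '", scope, "'")
  x[idx]
}

# Pearson r between 0/1 vectors from the overlap count, for every circular
# lag at once: r(m) = (L * o(m) - s1 * s2) / sqrt(s1 (L - s1) s2 (L - s2)).
binary_r_all_lags <- function(xi = NULL, xj = NULL, fi = NULL, fj = NULL,
                              s1, s2, L) {
  o <- circular_overlap_counts(a = xi, b = xj, fa = fi, fb = fj)
  den <- sqrt(s1 * (L - s1)) * sqrt(s2 * (L - s2))
  (L * o - s1 * s2) / den
}

#' Circular-shift permutation test for the correlation of one neuron pair
#'
#' Pearson correlation between two equal-length binarized trains, compared
#' with a null distribution obtained by circularly shifting the second train
#' by `n_shuffles` integer lags drawn uniformly from `1 .. length - 1`. The
#' pair is `correlated` when r is positive and strictly exceeds the 95th
#' percentile of the null; non-negative sub-threshold pairs are `random`;
#' negative correlations are `negative_excluded`; pairs with a constant train
#' are `ineligible`.
#'
#' @param x_i,x_j 0/1 vectors of equal length (already restricted to the
#'   analysis scope; see [state_concatenate()]).
#' @param n_shuffles Number of shuffles (default 2000).
#' @param seed Optional RNG seed.
#' @param percentile Null percentile (default 95).
#' @return A list: `r`, `null_p95`, `klass`.
#' @export
correlation_test <- function(x_i, x_j, n_shuffles = 2000, seed = NULL,
                             percentile = 95) {
  L <- length(x_i)
  stopifnot(length(x_j) == L)
  s1 <- sum(x_i); s2 <- sum(x_j)
  if (s1 %in% c(0L, L) || s2 %in% c(0L, L)) {
    return(list(r = NA_real_, null_p95 = NA_real_, klass = "ineligible"))
  }
  r_all <- binary_r_all_lags(xi = as.numeric(x_i), xj = as.numeric(x_j),
                             s1 = s1, s2 = s2, L = L)
  with_seed(seed, {
    lags <- sample.int(L - 1L, n_shuffles, replace = TRUE)
    null_r <- r_all[lags + 1L]
    p95 <- pct(null_r, percentile / 100)
    r <- r_all[1L]
    klass <- if (r < 0) "negative_excluded" else if (r > p95) "correlated" else "random"
    list(r = r, null_p95 = p95, klass = klass)
  })
}

#' Classify every eligible neuron pair of a session under one scope
#'
#' Runs [correlation_test()] on all centroid-eligible pairs, with the trains
#' restricted to the requested behavioral scope, and reports the fraction of
#' eligible pairs classified `correlated`. The circular shift is applied to
#' the concatenated state-restricted train of the higher-numbered cell, which
#' preserves state-specific event counts exactly.
#'
#' @param trains `n_samples x n_cells` 0/1 matrix.
#' @param seg A [segment_bouts()] result.
#' @param scope `"session"`, `"rest"` or `"run"`.
#' @param centroids Data frame with columns `x`, `y` in pixels (one row per
#'   cell), or `NULL` to treat all pairs as eligible.
#' @param n_shuffles,seed,percentile Passed to the per-pair test.
#' @param min_dist_px Minimum centroid distance in pixels.
#' @return A `pair_results` data frame (`i`, `j`, `scope`, `r`, `null_p95`,
#'   `klass`, `distance_um`) with attribute `correlated_fraction`.
#' @export
classify_session <- function(trains, seg, scope = c("session", "rest", "run"),
                             centroids = NULL, n_shuffles = 2000, seed = NULL,
                             percentile = 95, min_dist_px = 20) {
  scope <- match.arg(scope)
  n_cells <- ncol(trains)
  idx <- if (scope == "session") seq_len(nrow(trains)) else state_indices(seg, scope)
  if (!length(idx)) stop("classify_session: no samples in scope '", scope, "'")
  sub <- trains[idx, , drop = FALSE]
  L <- nrow(sub)
  sums <- colSums(sub)
  ffts <- stats::mvfft(sub * 1.0)
  pairs <- utils::combn(n_cells, 2L)
  with_seed(seed, {
    rows <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      dist_um <- NA_real_
      if (!is.null(centroids)) {
        d_px <- sqrt((centroids$x[i] - centroids$x[j])^2 +
                     (centroids$y[i] - centroids$y[j])^2)
        dist_um <- px_to_um(d_px)
        if (d_px < min_dist_px) {
          rows[[p]] <- data.frame(i = i, j = j, scope = scope, r = NA_real_,
                                  null_p95 = NA_real_, klass = "ineligible",
                                  distance_um = dist_um)
          next
        }
      }
      s1 <- sums[i]; s2 <- sums[j]
      if (s1 %in% c(0, L) || s2 %in% c(0, L)) {
        rows[[p]] <- data.frame(i = i, j = j, scope = scope, r = NA_real_,
                                null_p95 = NA_real_, klass = "ineligible",
                                distance_um = dist_um)
        next
      }
      r_all <- binary_r_all_lags(fi = ffts[, i], fj = ffts[, j],
                                 s1 = s1, s2 = s2, L = L)
      lags <- sample.int(L - 1L, n_shuffles, replace = TRUE)
      p95 <- pct(r_all[lags + 1L], percentile / 100)
      r <- r_all[1L]
      klass <- if (r < 0) "negative_excluded" else if (r > p95) "correlated" else "random"
      rows[[p]] <- data.frame(i = i, j = j, scope = scope, r = r,
                              null_p95 = p95, klass = klass,
                              distance_um = dist_um)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("pair_results", "data.frame")
    tested <- sum(out$klass != "ineligible")
    attr(out, "correlated_fraction") <-
      if (tested) sum(out$klass == "correlated") / tested else NA_real_
    out
  })
}

#' @export
print.pair_results <- function(x, ...) {
  cat(sprintf("Pair correlation results: %d pairs, scope '%s'\n",
              nrow(x), x$scope[1]))
  print(table(x$klass))
  cat(sprintf("Correlated fraction among eligible pairs: %.4f\n",
              attr(x, "correlated_fraction")))
  invisible(x)
}

#' Mean correlation of session-relevant pairs by modulation subgroup and state
#'
#' Session-relevant pairs (classified `correlated` on the full-session trains)
#' are split into Mod-Mod, Mod-Non and Non-Non subgroups by the movement
#' modulation of their members; within each subgroup, the Pearson r of every
#' pair is recomputed on the rest- and run-concatenated trains and averaged.
#'
#' @param session_pairs A `pair_results` data frame from
#'   `classify_session(..., scope = "session")`.
#' @param trains `n_samples x n_cells` 0/1 matrix.
#' @param seg A [segment_bouts()] result.
#' @param modulated Logical vector, one entry per cell.
#' @return Data frame `subgroup`, `state`, `mean_r`, `n_pairs` (`mean_r` is NA
#'   for empty subgroups).
#' @export
subgroup_means <- function(session_pairs, trains, seg, modulated) {
  rel <- session_pairs[session_pairs$klass == "correlated", , drop = FALSE]
  grp <- function(i, j) {
    m <- modulated[i] + modulated[j]
    c("Non-Non", "Mod-Non", "Mod-Mod")[m + 1L]
  }
  sub_of <- mapply(grp, rel$i, rel$j)
  out <- expand.grid(subgroup = c("Mod-Mod", "Mod-Non", "Non-Non"),
                     state = c("rest", "run"), stringsAsFactors = FALSE)
  out$mean_r <- NA_real_
  out$n_pairs <- 0L
  for (state in c("rest", "run")) {
    idx <- state_indices(seg, state)
    sub <- trains[idx, , drop = FALSE]
    r_state <- vapply(seq_len(nrow(rel)), function(p) {
      suppressWarnings(stats::cor(sub[, rel$i[p]], sub[, rel$j[p]]))
    }, numeric(1))
    for (g in c("Mod-Mod", "Mod-Non", "Non-Non")) {
      sel <- sub_of == g & is.finite(r_state)
      row <- out$subgroup == g & out$state == state
      out$n_pairs[row] <- sum(sel)
      if (any(sel)) out$mean_r[row] <- mean(r_state[sel])
    }
  }
  out
}

#' Shuffled correlation versus event rate (rate-control analysis)
#'
#' For every eligible pair, the train of one cell is circularly shifted by
#' `n_shuffles` random lags (uniform over the scope length) and the Pearson r
#' of each shuffle is recorded together with the pair's mean event rate, to
#' check whether event rate alone inflates chance correlations.
#'
#' @param trains `n_samples x n_cells` 0/1 matrix.
#' @param seg A [segment_bouts()] result.
#' @param scope `"rest"` or `"run"`.
#' @param n_shuffles Shuffles per pair (default 100).
#' @param seed Optional RNG seed.
#' @return Data frame `i`, `j`, `mean_rate_ev_min` (pair mean of events/min in
#'   the scope, events counted as 0-to-1 transitions of the train), and
#'   `r_shuffled` (`n_shuffles` rows per pair).
#' @export
rate_correlation_control <- function(trains, seg, scope = c("rest", "run"),
                                     n_shuffles = 100, seed = NULL) {
  scope <- match.arg(scope)
  idx <- state_indices(seg, scope)
  sub <- trains[idx, , drop = FALSE]
  L <- nrow(sub)
  t_min <- L / seg$fs / 60
  onset_counts <- vapply(seq_len(ncol(sub)), function(c) {
    x <- sub[, c]
    sum(diff(c(0L, x)) == 1L)
  }, numeric(1))
  rates <- onset_counts / t_min
  sums <- colSums(sub)
  ffts <- stats::mvfft(sub * 1.0)
  pairs <- utils::combn(ncol(sub), 2L)
  with_seed(seed, {
    rows <- vector("list", ncol(pairs))
    for (p in seq_len(ncol(pairs))) {
      i <- pairs[1L, p]; j <- pairs[2L, p]
      s1 <- sums[i]; s2 <- sums[j]
      if (s1 %in% c(0, L) || s2 %in% c(0, L)) next
      r_all <- binary_r_all_lags(fi = ffts[, i], fj = ffts[, j],
                                 s1 = s1, s2 = s2, L = L)
      lags <- sample.int(L - 1L, n_shuffles, replace = TRUE)
      rows[[p]] <- data.frame(i = i, j = j,
                              mean_rate_ev_min = (rates[i] + rates[j]) / 2,
                              r_shuffled = r_all[lags + 1L])
    }
    do.call(rbind, rows)
  })
}
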