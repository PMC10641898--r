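#' Binarize a trace into an event train
#'
#' Ones over the entire rising phase (`t_on` to `t_peak`, inclusive) of each
#' detected calcium event, zeros elsewhere. Only the rising phase is used, to
#' avoid inflating correlations through the slow indicator decay.
#'
#' @param events A `calcium_events` data frame (or any data frame with `t_on`,
#'   `t_peak` sample indices).
#' @param n_samples Trace length in samples.
#' @return Integer 0/1 vector of length `n_samples`.
#' @export
binarize <- function(events, n_samples) {
  x <- integer(n_samples)
  for (i in seq_len(nrow(events))) {
    x[events$t_on[i]:events$t_peak[i]] <- 1L
  }
  x
}

#' Movement-activity metric A
#'
#' Difference between the binarized-event density during running and during
#' resting, in percent:
#' \eqn{A = 100 (\sum_{run} x / \sum_{run} t - \sum_{rest} x / \sum_{rest} t)},
#' where both sums run over the concatenated samples of the state and time is
#' counted in samples.
#'
#' @param x Binarized 0/1 train.
#' @param seg A [segment_bouts()] result.
#' @return The activity metric in percent.
#' @export
activity_metric <- function(x, seg) {
  run_idx <- state_indices(seg, "run")
  rest_idx <- state_indices(seg, "rest")
  if (!length(run_idx) || !length(rest_idx)) {
    stop("activity_metric: session has no time in one behavioral state")
  }
  100 * (sum(x[run_idx]) / length(run_idx) - sum(x[rest_idx]) / length(rest_idx))
}

# Activity metric for every circular forward shift of `x` at once, via FFT
# cross-correlation with the state indicator vectors. Element m + 1 is the
# metric after shifting `x` by lag m.
activity_metric_all_lags <- function(x, seg, f_run = NULL, f_rest = NULL) {
  n <- seg$n_samples
  run_idx <- state_indices(seg, "run")
  rest_idx <- state_indices(seg, "rest")
  if (!length(run_idx) || !length(rest_idx)) {
    stop("activity_metric: session has no time in one behavioral state")
  }
  if (is.null(f_run)) {
    ind <- numeric(n); ind[run_idx] <- 1
    f_run <- stats::fft(ind)
  }
  if (is.null(f_rest)) {
    ind <- numeric(n); ind[rest_idx] <- 1
    f_rest <- stats::fft(ind)
  }
  fx <- stats::fft(as.numeric(x))
  s_run <- circular_overlap_counts(fa = f_run, fb = fx)
  s_rest <- circular_overlap_counts(fa = f_rest, fb = fx)
  100 * (s_run / length(run_idx) - s_rest / length(rest_idx))
}

#' Circular-shift permutation test for movement modulation of one cell
#'
#' The observed activity metric [activity_metric()] is compared with a null
#' distribution built by circularly shifting the binarized train relative to
#' the movement trace by integer lags drawn uniformly from `1 .. length - 1`,
#' `n_shuffles` times. The cell is movement-modulated when the observed metric
#' strictly exceeds the 97.5th percentile of the null.
#'
#' @param x Binarized 0/1 train.
#' @param seg A [segment_bouts()] result.
#' @param n_shuffles Number of shuffles (default 1000).
#' @param seed Optional RNG seed.
#' @param percentile Null percentile defining the threshold (default 97.5).
#' @return A `modulation_result` list: `A_obs` (percent), `null_A`,
#'   `threshold`, `is_modulated`.
#' @export
modulation_test <- function(x, seg, n_shuffles = 1000, seed = NULL,
                            percentile = 97.5) {
  A_all <- activity_metric_all_lags(x, seg)
  with_seed(seed, {
    n <- seg$n_samples
    lags <- sample.int(n - 1L, n_shuffles, replace = TRUE)
    null_A <- A_all[lags + 1L]
    threshold <- pct(null_A, percentile / 100)
    out <- list(
      A_obs = A_all[1L],
      null_A = null_A,
      threshold = threshold,
      is_modulated = A_all[1L] > threshold
    )
    class(out) <- "modulation_result"
    out
  })
}

#' @export
print.modulation_result <- function(x, ...) {
  cat(sprintf(
    "Movement modulation: A = %.3f%%, null 97.5th pct = %.3f%% -> %s\n",
    x$A_obs, x$threshold,
    if (x$is_modulated) "MODULATED" else "not modulated"
  ))
  invisible(x)
}

#' Movement-modulation classification for a population of cells
#'
#' Applies [modulation_test()] to every column of a binarized-train matrix,
#' reusing the state-indicator spectra across cells.
#'
#' @param trains `n_samples x n_cells` 0/1 matrix.
#' @param seg A [segment_bouts()] result.
#' @inheritParams modulation_test
#' @return Data frame with one row per cell: `cell`, `A_obs`, `threshold`,
#'   `is_modulated`.
#' @export
modulation_table <- function(trains, seg, n_shuffles = 1000, seed = NULL,
                             percentile = 97.5) {
  n <- seg$n_samples
  stopifnot(nrow(trains) == n)
  run_idx <- state_indices(seg, "run")
  rest_idx <- state_indices(seg, "rest")
  ind_run <- numeric(n); ind_run[run_idx] <- 1
  ind_rest <- numeric(n); ind_rest[rest_idx] <- 1
  f_run <- stats::fft(ind_run)
  f_rest <- stats::fft(ind_rest)
  with_seed(seed, {
    res <- lapply(seq_len(ncol(trains)), function(cell) {
      A_all <- activity_metric_all_lags(trains[, cell], seg,
                                        f_run = f_run, f_rest = f_rest)
      lags <- sample.int(n - 1L, n_shuffles, replace = TRUE)
      null_A <- A_all[lags + 1L]
      thr <- pct(null_A, percentile / 100)
      data.frame(cell = cell, A_obs = A_all[1L], threshold = thr,
                 is_modulated = A_all[1L] > thr)
    })
    do.call(rbind, res)
  })
}
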