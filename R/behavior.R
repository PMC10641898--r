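#' Linear running speed from two-sensor treadmill displacement
#'
#' A spherical treadmill reports surface displacement through two optical
#' sensors mounted at the ball's equator, an angle `theta` apart. The vertical
#' readings of the two sensors are combined into perpendicular velocity
#' components \eqn{X = (L - R\cos\theta)/\sin\theta}, \eqn{Y = R}, and the
#' linear speed \eqn{V = \sqrt{X^2 + Y^2}}. The speed trace is then linearly
#' interpolated onto a uniform 20 Hz grid.
#'
#' @param L,R Numeric vectors of equal length: vertical readings (cm/s) of the
#'   left and right sensors.
#' @param theta Angle between the sensors in radians, in (0, pi). The
#'   experimental rigs used approximately 78 degrees.
#' @param fs_in Sampling rate of `L` and `R` in Hz.
#' @param fs_out Output sampling rate in Hz (default 20).
#' @return A `speed_trace` data frame with columns `t` (seconds) and `v`
#'   (cm/s), and attribute `fs`.
#' @examples
#' sp <- compute_velocity(L = rep(3, 100), R = rep(4, 100), theta = pi / 2)
#' head(sp$v) # orthogonal sensors: sqrt(3^2 + 4^2) = 5
#' @export
compute_velocity <- function(L, R, theta = 78 * pi / 180, fs_in = 20, fs_out = 20) {
  if (length(L) != length(R)) stop("`L` and `R` must have the same length")
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= pi ||
      abs(sin(theta)) < .Machine$double.eps^0.5) {
    stop("`theta` must lie strictly inside (0, pi): sensor geometry is degenerate otherwise")
  }
  X <- (L - R * cos(theta)) / sin(theta)
  Y <- R
  V <- sqrt(X^2 + Y^2)
  t_in <- (seq_along(V) - 1) / fs_in
  if (fs_in == fs_out) {
    return(speed_trace(V, fs = fs_out))
  }
  t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_out)
  v_out <- stats::approx(t_in, V, xout = t_out, rule = 2)$y
  speed_trace(v_out, fs = fs_out)
}

#' Construct a speed trace
#'
#' @param v Non-negative speed values in cm/s, uniformly sampled.
#' @param fs Sampling rate in Hz.
#' @return A `speed_trace` data frame with columns `t` and `v`.
#' @export
speed_trace <- function(v, fs = 20) {
  stopifnot(is.numeric(v), length(v) >= 1L, fs > 0)
  out <- data.frame(t = (seq_along(v) - 1) / fs, v = as.numeric(v))
  attr(out, "fs") <- fs
  class(out) <- c("speed_trace", "data.frame")
  out
}

#' Sigmoidal fuzzy membership of a speed sample in the "running" state
#'
#' \eqn{F(V) = 1 / (1 + e^{-a (V - c)})}: 0.5 at the threshold `c`, saturating
#' towards 1 for high speeds.
#'
#' @param v Speed values, cm/s.
#' @param a Sigmoid steepness (> 0), default 0.8.
#' @param c Speed threshold in cm/s (the sigmoid midpoint).
#' @return Membership values in (0, 1).
#' @export
fuzzy_membership <- function(v, a = 0.8, c) {
  if (!is.numeric(a) || a <= 0) stop("`a` must be positive")
  1 / (1 + exp(-a * (v - c)))
}

#' Segment a speed trace into rest and run bouts
#'
#' Fuzzy-logic thresholding of running speed. Each sample's speed is mapped to
#' a sigmoidal membership value with midpoint `c = max(20th percentile of the
#' session's speed, 5 cm/s)`; the membership trace is smoothed with a centered
#' moving average of `smooth_s` seconds and thresholded at `frac_thresh` of its
#' session maximum. Supra-threshold stretches at least `min_s` seconds long are
#' labeled `run`, sub-threshold stretches at least `min_s` long are labeled
#' `rest`, and everything else is `unclassified`. Samples exactly at the
#' threshold count as supra-threshold.
#'
#' For degenerate sessions in which the animal never moves, the smoothed
#' membership trace is nearly constant at its resting floor; thresholding such
#' a trace against a fraction of its own maximum would label the whole session
#' as running. The threshold maximum is therefore floored at the sigmoid
#' midpoint value 0.5 (the membership of a sample moving exactly at `c`), so an
#' all-quiet session is labeled as one long rest bout.
#'
#' @param speed A `speed_trace` (or numeric speed vector sampled at `fs`).
#' @param a Sigmoid steepness, default 0.8.
#' @param smooth_s Moving-average window in seconds, default 1.5.
#' @param frac_thresh Fraction of the smoothed-membership maximum used as the
#'   run threshold, default 0.10.
#' @param min_s Minimum bout duration in seconds, default 2.
#' @param c_floor Lower bound on the speed threshold `c` in cm/s, default 5.
#' @param c_quantile Quantile of the session speed defining `c`, default 0.20.
#' @param fs Sampling rate, used only when `speed` is a bare numeric vector.
#' @return A `bout_segmentation`: list with `intervals` (data frame of
#'   `start`, `end` 1-based inclusive sample indices and `label`), `fs`,
#'   `n_samples` and `params`.
#' @export
segment_bouts <- function(speed, a = 0.8, smooth_s = 1.5, frac_thresh = 0.10,
                          min_s = 2, c_floor = 5, c_quantile = 0.20, fs = 20) {
  if (inherits(speed, "speed_trace")) {
    v <- speed$v
    fs <- attr(speed, "fs")
  } else {
    v <- as.numeric(speed)
  }
  if (length(v) == 0L) stop("`speed` must be non-empty")
  c_thr <- max(pct(v, c_quantile), c_floor)
  m <- fuzzy_membership(v, a = a, c = c_thr)
  m_sm <- moving_average(m, round(smooth_s * fs))
  thr <- frac_thresh * max(max(m_sm), 0.5)
  supra <- m_sm >= thr
  supra_raw <- m >= thr
  min_n <- ceiling(min_s * fs)

  # candidate intervals come from the smoothed trace (stable against jitter);
  # their boundaries are then refined to the raw membership crossings, so the
  # smoothing window does not stretch a bout beyond the actual high- or
  # low-velocity samples
  n <- length(v)
  label <- rep("unclassified", n)
  for (state in c("run", "rest")) {
    flag <- if (state == "run") supra else !supra
    raw_flag <- if (state == "run") supra_raw else !supra_raw
    runs <- logical_runs(flag)
    for (k in seq_len(nrow(runs))) {
      inside <- which(raw_flag[runs$start[k]:runs$end[k]])
      if (!length(inside)) next
      s0 <- runs$start[k] + inside[1L] - 1L
      s1 <- runs$start[k] + inside[length(inside)] - 1L
      if (s1 - s0 + 1L >= min_n) label[s0:s1] <- state
    }
  }
  r <- rle(label)
  ends <- cumsum(r$lengths)
  intervals <- data.frame(
    start = ends - r$lengths + 1L,
    end = ends,
    label = r$values,
    stringsAsFactors = FALSE
  )
  out <- list(
    intervals = intervals,
    fs = fs,
    n_samples = n,
    params = list(a = a, c = c_thr, smooth_s = smooth_s,
                  frac_thresh = frac_thresh, min_s = min_s)
  )
  class(out) <- "bout_segmentation"
  out
}

#' @export
print.bout_segmentation <- function(x, ...) {
  tab <- table(factor(x$intervals$label, c("rest", "run", "unclassified")))
  cat(sprintf(
    "Bout segmentation: %d samples at %g Hz (%.1f s)\n", x$n_samples, x$fs,
    x$n_samples / x$fs
  ))
  cat(sprintf("  rest bouts: %d (%.1f s), run bouts: %d (%.1f s), unclassified: %d (%.1f s)\n",
              tab[["rest"]], state_time(x, "rest"),
              tab[["run"]], state_time(x, "run"),
              tab[["unclassified"]], state_time(x, "unclassified")))
  cat(sprintf("  fuzzy params: a = %g, c = %.2f cm/s, min bout = %g s\n",
              x$params$a, x$params$c, x$params$min_s))
  invisible(x)
}

#' Sample indices belonging to one behavioral state
#'
#' @param seg A `bout_segmentation`.
#' @param state One of `"rest"`, `"run"`, `"unclassified"`.
#' @return Integer vector of 1-based sample indices, in temporal order.
#' @export
state_indices <- function(seg, state) {
  iv <- seg$intervals[seg$intervals$label == state, , drop = FALSE]
  if (nrow(iv) == 0L) return(integer(0))
  unlist(lapply(seq_len(nrow(iv)), function(k) iv$start[k]:iv$end[k]),
         use.names = FALSE)
}

#' Total time spent in one behavioral state, in seconds
#'
#' @inheritParams state_indices
#' @export
state_time <- function(seg, state) {
  iv <- seg$intervals[seg$intervals$label == state, , drop = FALSE]
  sum(iv$end - iv$start + 1L) / seg$fs
}

#' Session-level quality control for locomotion analysis
#'
#' A session enters locomotion-conditioned analyses only when the animal spent
#' at least `min_state_s` seconds (default 60 s, 10% of a 10-minute session) in
#' each behavioral state and produced at least `min_run_bouts` running bouts.
#'
#' @param seg A `bout_segmentation`.
#' @param min_state_s Minimum time in each state, seconds.
#' @param min_run_bouts Minimum number of running bouts.
#' @return A list with `time_in_rest_s`, `time_in_run_s`, `n_run_bouts` and
#'   `eligible_for_locomotion_analysis`.
#' @export
session_qc <- function(seg, min_state_s = 60, min_run_bouts = 5) {
  time_rest <- state_time(seg, "rest")
  time_run <- state_time(seg, "run")
  n_run <- sum(seg$intervals$label == "run")
  list(
    time_in_rest_s = time_rest,
    time_in_run_s = time_run,
    n_run_bouts = n_run,
    eligible_for_locomotion_analysis =
      min(time_rest, time_run) >= min_state_s && n_run >= min_run_bouts
  )
}

#' Kinematic summary of running bouts
#'
#' @param speed A `speed_trace` aligned with `seg`.
#' @param seg A `bout_segmentation`.
#' @return A list with `n_bouts`, `mean_bout_duration_s`, `mean_bout_speed`
#'   (mean of per-bout mean speeds, cm/s) and `session_mean_speed`.
#' @export
bout_kinematics <- function(speed, seg) {
  v <- if (inherits(speed, "speed_trace")) speed$v else as.numeric(speed)
  stopifnot(length(v) == seg$n_samples)
  iv <- seg$intervals[seg$intervals$label == "run", , drop = FALSE]
  durations <- (iv$end - iv$start + 1L) / seg$fs
  bout_speed <- vapply(seq_len(nrow(iv)),
                       function(k) mean(v[iv$start[k]:iv$end[k]]), numeric(1))
  list(
    n_bouts = nrow(iv),
    mean_bout_duration_s = if (nrow(iv)) mean(durations) else NA_real_,
    mean_bout_speed = if (nrow(iv)) mean(bout_speed) else NA_real_,
    session_mean_speed = mean(v)
  )
}
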