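#' Calcium event detector parameters
#'
#' All thresholds of the spectrogram-based iterative detector. Defaults follow
#' the published procedure: multitaper spectrogram with time-bandwidth 2 and 3
#' tapers over 1-s windows stepped every 0.05 s, power averaged below 2 Hz;
#' power-change outliers at 3 scaled median absolute deviations; iteration 1
#' accepts candidates whose amplitude exceeds 7 SDs of the trace in the 10 s
#' before onset; each further iteration lowers the threshold by 40% and grows
#' the lookback window by 75%; rise times must span at least 3 samples
#' (150 ms at 20 Hz).
#'
#' @param power_band_hz Average spectrogram power below this frequency.
#' @param window_s,step_s Spectrogram window and step, seconds.
#' @param nw,k_tapers Multitaper time-bandwidth product and taper count.
#' @param mad_k Outlier threshold in scaled MADs.
#' @param sd0 Iteration-1 amplitude threshold in SD units.
#' @param sd_decay Per-iteration threshold decrease (fraction in (0, 1]).
#' @param win0_s Iteration-1 lookback window, seconds.
#' @param win_growth Per-iteration window growth (fraction in (0, 1]).
#' @param min_rise_s Minimum rise time, seconds.
#' @param method `"multitaper"` (DPSS) or `"stft"` (single-taper fallback).
#' @return A `detector_params` list.
#' @export
detector_params <- function(power_band_hz = 2, window_s = 1, step_s = 0.05,
                            nw = 2, k_tapers = 3, mad_k = 3,
                            sd0 = 7, sd_decay = 0.40,
                            win0_s = 10, win_growth = 0.75,
                            min_rise_s = 0.15,
                            method = c("multitaper", "stft")) {
  p <- list(power_band_hz = power_band_hz, window_s = window_s, step_s = step_s,
            nw = nw, k_tapers = k_tapers, mad_k = mad_k, sd0 = sd0,
            sd_decay = sd_decay, win0_s = win0_s, win_growth = win_growth,
            min_rise_s = min_rise_s, method = match.arg(method))
  stopifnot(all(vapply(p[1:11], function(z) is.numeric(z) && z > 0, logical(1))))
  if (p$sd_decay > 1 || p$win_growth > 1) {
    stop("`sd_decay` and `win_growth` must lie in (0, 1]")
  }
  class(p) <- "detector_params"
  p
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the DPSS sequences; the `k` most concentrated tapers are
#' returned orthonormal (columns with unit energy).
#'
#' @param n Sequence length.
#' @param nw Time-bandwidth product.
#' @param k Number of tapers.
#' @return `n x k` matrix of tapers.
#' @export
dpss_tapers <- function(n, nw = 2, k = 3) {
  stopifnot(n >= 2, k >= 1, k <= n, nw > 0, nw < n / 2)
  W <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  A <- diag(diag_main)
  A[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- off
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1L)] <- off
  e <- eigen(A, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # conventional polarity: symmetric tapers have positive mean
  for (j in seq_len(k)) {
    s <- sum(v[, j])
    if (abs(s) > 1e-12 && s < 0) v[, j] <- -v[, j]
  }
  v
}

#' Low-frequency spectrogram power of a fluorescence trace
#'
#' The trace is smoothed with a 1-s moving average, split into sliding windows
#' (window mean removed), tapered, and the short-time power spectrum is
#' averaged over the tapers and over all frequencies below `power_band_hz`.
#'
#' @param trace Numeric dF/F trace.
#' @param fs Sampling rate, Hz.
#' @param params A [detector_params()].
#' @return A list with `power` (one value per window), `center_idx` (trace
#'   sample index at each window center), and `step` (samples between windows).
#' @export
lowfreq_power <- function(trace, fs = 20, params = detector_params()) {
  win <- round(params$window_s * fs)
  if (length(trace) < win) stop("lowfreq_power: trace shorter than the window")
  step <- max(1L, round(params$step_s * fs))
  xs <- moving_average(trace, round(1 * fs))
  starts <- seq(1L, length(xs) - win + 1L, by = step)
  X <- matrix(xs[outer(0:(win - 1L), starts, "+")], nrow = win)
  X <- sweep(X, 2, colMeans(X))
  freqs <- (0:(win - 1)) * fs / win
  sel <- which(freqs < params$power_band_hz & freqs <= fs / 2)
  if (params$method == "multitaper") {
    tap <- dpss_tapers(win, params$nw, params$k_tapers)
  } else {
    tap <- matrix(rep(1 / sqrt(win), win), ncol = 1)
  }
  pow <- 0
  for (j in seq_len(ncol(tap))) {
    pow <- pow + Mod(stats::mvfft(X * tap[, j]))^2
  }
  pow <- pow / ncol(tap)
  list(
    power = colMeans(pow[sel, , drop = FALSE]),
    center_idx = starts + win %/% 2L,
    step = step
  )
}

#' Candidate event groups from a power series
#'
#' First-differences the power series, flags outliers more than `mad_k` scaled
#' median absolute deviations from the median difference, and merges
#' consecutive flagged samples into candidate groups.
#'
#' @param power Numeric power series.
#' @param mad_k Outlier threshold in scaled MADs (default 3).
#' @return Data frame with `start`, `end` (indices into `diff(power)`) and
#'   `rising` (whether the group's mean power change is positive).
#' @export
candidate_events <- function(power, mad_k = 3) {
  if (length(power) < 2L) stop("candidate_events: need at least 2 power samples")
  pd <- diff(power)
  med <- stats::median(pd)
  s <- stats::mad(pd) # scaled MAD, consistency factor 1.4826
  flag <- abs(pd - med) > mad_k * s
  groups <- logical_runs(flag)
  if (nrow(groups) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), rising = logical(0)))
  }
  groups$rising <- vapply(seq_len(nrow(groups)), function(k) {
    mean(pd[groups$start[k]:groups$end[k]]) > 0
  }, logical(1))
  groups
}

# Onset for a given peak sample: last crossing of 10% of the local height
# before the peak, against a median pre-peak baseline. The median baseline is
# robust to the rise itself and, for pure-noise candidates, keeps
# peak-minus-onset heights near the noise SD; a peak at or below the local
# median (e.g. a ripple on a decay) is rejected.
onset_for_peak <- function(sm, t_peak, fs) {
  base_lo <- max(1L, t_peak - 2L * fs)
  if (t_peak - base_lo < 2L) return(NULL)
  seg <- sm[base_lo:t_peak]
  b <- stats::median(seg)
  if (sm[t_peak] <= b) return(NULL)
  thr <- b + 0.1 * (sm[t_peak] - b)
  below <- which(seg[-length(seg)] <= thr)
  if (!length(below)) return(NULL)
  t_on <- base_lo - 1L + unname(max(below))
  if (t_on >= t_peak) return(NULL)
  c(t_on = as.integer(t_on), t_peak = as.integer(t_peak))
}

# All candidate (t_on, t_peak) pairs inside one power-outlier group span:
# every local maximum of the smoothed trace gets its own onset, so that
# transients close enough to share one outlier run are still separated.
locate_candidates <- function(trace, sm, tc, tc_end, fs) {
  n <- length(trace)
  lo <- max(1L, tc - round(0.25 * fs))
  hi <- min(n, tc_end + round(0.5 * fs))
  seg <- sm[lo:hi]
  pk <- which(diff(sign(diff(seg))) < 0) + 1L
  if (length(seg) > 1L) {
    if (seg[1] > seg[2]) pk <- c(1L, pk)
    if (seg[length(seg)] > seg[length(seg) - 1L]) pk <- c(pk, length(seg))
  }
  out <- list()
  for (p in lo - 1L + pk) {
    loc <- onset_for_peak(sm, p, fs)
    if (!is.null(loc)) out[[length(out) + 1L]] <- loc
  }
  out
}

# First sample after the peak falling below the onset value (the "end of the
# event fall"), capped at the next candidate onset / trace end.
fall_end <- function(trace, t_on, t_peak, cap) {
  j <- t_peak
  lim <- min(cap, length(trace))
  while (j < lim && trace[j + 1L] >= trace[t_on]) j <- j + 1L
  min(j + 1L, lim)
}

#' Detect calcium events in a normalized fluorescence trace
#'
#' Candidate onsets come from positive outliers in the change of low-frequency
#' spectrogram power ([lowfreq_power()], [candidate_events()]). Each candidate
#' is located on the trace (peak, onset, amplitude, rise time) and accepted by
#' an iterative amplitude test: iteration `k` (k = 0, 1, ...) accepts a
#' candidate when its rise spans at least 3 samples and its amplitude exceeds
#' `sd0 * (1 - sd_decay)^k` times the SD of the trace in the
#' `win0_s * (1 + win_growth)^k`-second window before onset, with samples of
#' previously accepted events excluded from that window (candidates with fewer
#' than 20 usable window samples are deferred to the next iteration). Accepted
#' events' samples (rise through fall) are removed before the next iteration;
#' the procedure stops when an iteration accepts nothing.
#'
#' @param trace Normalized dF/F trace in [0, 1].
#' @param fs Sampling rate, Hz.
#' @param params A [detector_params()].
#' @return A `calcium_events` data frame: `t_on`, `t_peak` (sample indices),
#'   `amplitude`, `rise_s`, `fwhm_s`, `fwhm_excluded_reason`
#'   (`"none"`, `"next_event_overlap"` or `"multi_peak"`).
#' @export
detect_events <- function(trace, fs = 20, params = detector_params()) {
  empty <- data.frame(
    t_on = integer(0), t_peak = integer(0), amplitude = numeric(0),
    rise_s = numeric(0), fwhm_s = numeric(0),
    fwhm_excluded_reason = character(0), stringsAsFactors = FALSE
  )
  class(empty) <- c("calcium_events", "data.frame")
  n <- length(trace)
  lp <- lowfreq_power(trace, fs, params)
  groups <- candidate_events(lp$power, params$mad_k)
  groups <- groups[groups$rising, , drop = FALSE]
  if (nrow(groups) == 0L) return(empty)

  # a real transient elevates the power of every sliding window it overlaps,
  # so its outlier run must span at least window_s / step_s consecutive steps
  min_group <- round(params$window_s / params$step_s)
  groups <- groups[groups$end - groups$start + 1L >= min_group, , drop = FALSE]
  if (nrow(groups) == 0L) return(empty)

  sm <- moving_average(unname(trace), 5L)
  min_rise_n <- round(params$min_rise_s * fs)
  cand <- list()
  for (g in seq_len(nrow(groups))) {
    # diff index i measures the change between power windows i and i + 1
    pi_idx <- min(groups$start[g] + 1L, length(lp$center_idx))
    pe_idx <- min(groups$end[g] + 1L, length(lp$center_idx))
    locs <- locate_candidates(trace, sm, lp$center_idx[pi_idx],
                              lp$center_idx[pe_idx], fs)
    for (loc in locs) {
      amp <- sm[loc[["t_peak"]]] - sm[loc[["t_on"]]]
      if (amp <= 0) next
      if (loc[["t_peak"]] - loc[["t_on"]] < min_rise_n) next
      cand[[length(cand) + 1L]] <- loc
    }
  }
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[!duplicated(cand[, "t_peak"]), , drop = FALSE]
  cand <- cand[order(cand[, "t_on"], cand[, "t_peak"]), , drop = FALSE]
  # candidates whose rising phases overlap describe the same transient (noise
  # ripples on one rise): keep the tallest of each overlap chain
  amp_all <- sm[cand[, "t_peak"]] - sm[cand[, "t_on"]]
  keep <- integer(0)
  chain <- 1L
  chain_end <- cand[1L, "t_peak"]
  best <- 1L
  for (i in seq_len(nrow(cand))[-1L]) {
    if (cand[i, "t_on"] <= chain_end) {
      chain_end <- max(chain_end, cand[i, "t_peak"])
      if (amp_all[i] > amp_all[best]) best <- i
    } else {
      keep <- c(keep, best)
      best <- i
      chain_end <- cand[i, "t_peak"]
    }
  }
  keep <- c(keep, best)
  cand <- cand[keep, , drop = FALSE]
  t_on <- cand[, "t_on"]; t_peak <- cand[, "t_peak"]
  amp <- sm[t_peak] - sm[t_on]
  n_cand <- length(t_on)
  next_on <- c(t_on[-1L], n + 1L)
  f_end <- vapply(seq_len(n_cand), function(i) {
    fall_end(trace, t_on[i], t_peak[i], next_on[i])
  }, numeric(1))

  avail <- rep(TRUE, n)
  pending <- seq_len(n_cand)
  accepted <- integer(0)
  k <- 0L
  repeat {
    factor <- params$sd0 * (1 - params$sd_decay)^k
    win_n <- round(params$win0_s * (1 + params$win_growth)^k * fs)
    newly <- integer(0)
    for (ci in pending) {
      if (t_on[ci] <= 1L) next
      idx <- seq.int(max(1L, t_on[ci] - win_n), t_on[ci] - 1L)
      idx <- idx[avail[idx]]
      if (length(idx) < 20L) next # deferred: too few usable samples
      if (amp[ci] > factor * stats::sd(trace[idx])) newly <- c(newly, ci)
    }
    if (!length(newly)) break
    accepted <- c(accepted, newly)
    pending <- setdiff(pending, newly)
    for (ci in newly) avail[t_on[ci]:f_end[ci]] <- FALSE
    if (!length(pending)) break
    k <- k + 1L
  }
  if (!length(accepted)) return(empty)
  accepted <- sort(accepted)
  out <- data.frame(
    t_on = as.integer(t_on[accepted]),
    t_peak = as.integer(t_peak[accepted]),
    amplitude = amp[accepted],
    rise_s = (t_peak[accepted] - t_on[accepted]) / fs,
    stringsAsFactors = FALSE
  )
  fw <- lapply(seq_len(nrow(out)), function(i) {
    event_metrics(out$t_on[i], out$t_peak[i], trace, fs,
                  next_on = if (i < nrow(out)) out$t_on[i + 1L] else n + 1L,
                  sm = sm)
  })
  out$fwhm_s <- vapply(fw, `[[`, numeric(1), "fwhm_s")
  out$fwhm_excluded_reason <- vapply(fw, `[[`, character(1), "reason")
  class(out) <- c("calcium_events", "data.frame")
  out
}

#' @export
print.calcium_events <- function(x, ...) {
  cat(sprintf("%d calcium event(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Rise time and full width at half maximum of one event
#'
#' Height is the trace value at the peak minus the value at onset. FWHM is the
#' time between the 50%-height crossings on the rise and on the decay
#' (sub-sample linear interpolation). It is excluded when a subsequent event
#' onset occurs before the decay crossing (`next_event_overlap`) or when the
#' event shows more than one peak above 75% of its height (`multi_peak`,
#' counted as upward crossings of the 75% level on a lightly smoothed trace).
#'
#' @param t_on,t_peak Onset and peak sample indices.
#' @param trace The normalized trace.
#' @param fs Sampling rate, Hz.
#' @param next_on Onset index of the next detected event (or past-the-end).
#' @param sm Optional pre-smoothed trace (3-sample moving average).
#' @return A list with `rise_s`, `fwhm_s` (NA when excluded) and `reason`.
#' @export
event_metrics <- function(t_on, t_peak, trace, fs = 20,
                          next_on = length(trace) + 1L, sm = NULL) {
  if (is.null(sm)) sm <- moving_average(trace, 5L)
  n <- length(trace)
  h <- trace[t_peak] - trace[t_on]
  half <- trace[t_on] + h / 2
  rise_s <- (t_peak - t_on) / fs

  # rising half-height crossing: last upward crossing before the peak
  ri <- NA_real_
  for (i in seq.int(t_peak - 1L, t_on)) {
    if (trace[i] <= half && trace[i + 1L] > half) {
      ri <- i + (half - trace[i]) / (trace[i + 1L] - trace[i])
      break
    }
  }
  # decaying half-height crossing
  di <- NA_real_
  j <- t_peak
  while (j < n) {
    if (trace[j + 1L] < half) {
      di <- j + (trace[j] - half) / (trace[j] - trace[j + 1L])
      break
    }
    j <- j + 1L
  }
  if (is.na(ri) || is.na(di)) {
    return(list(rise_s = rise_s, fwhm_s = NA_real_,
                reason = "next_event_overlap"))
  }
  if (next_on <= di) {
    return(list(rise_s = rise_s, fwhm_s = NA_real_,
                reason = "next_event_overlap"))
  }
  # multi-peak screen: upward crossings of the 75% level within the event span
  span_end <- min(n, ceiling(di) + 1L)
  thr75 <- trace[t_on] + 0.75 * h
  seg <- sm[t_on:span_end]
  up <- sum(seg[-length(seg)] <= thr75 & seg[-1L] > thr75)
  if (up > 1L) {
    return(list(rise_s = rise_s, fwhm_s = NA_real_, reason = "multi_peak"))
  }
  list(rise_s = rise_s, fwhm_s = (di - ri) / fs, reason = "none")
}

#' Calcium event rate, overall or conditioned on a behavioral state
#'
#' @param events A `calcium_events` data frame.
#' @param seg A [segment_bouts()] result (required for state-conditioned
#'   rates).
#' @param state `"session"`, `"rest"` or `"run"`.
#' @param n_samples,fs Trace length and sampling rate for `state = "session"`
#'   when `seg` is not given.
#' @return Events per minute.
#' @export
event_rate <- function(events, seg = NULL, state = "session",
                       n_samples = NULL, fs = 20) {
  if (state == "session") {
    if (!is.null(seg)) {
      n_samples <- seg$n_samples
      fs <- seg$fs
    }
    stopifnot(!is.null(n_samples))
    return(nrow(events) / (n_samples / fs) * 60)
  }
  stopifnot(!is.null(seg))
  t_state <- state_time(seg, state)
  if (t_state <= 0) stop("event_rate: no time spent in state '", state, "'")
  idx <- state_indices(seg, state)
  in_state <- logical(seg$n_samples)
  in_state[idx] <- TRUE
  sum(in_state[events$t_on]) / t_state * 60
}
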