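#' Configuration for the synthetic calcium-imaging session generator
#'
#' Bundles every knob of the simulator with defaults chosen to emulate the
#' study conditions of a head-fixed mouse on a spherical treadmill imaged at
#' 20 Hz: 10-minute sessions, sparse calcium events (~1.7 events/min at rest
#' and ~2.8 events/min during running for movement-modulated cells), roughly
#' twenty running bouts with a mean duration near 12 s, and an event kernel
#' with a fast linear rise and an exponential decay.
#'
#' @param duration_s Session duration in seconds (default 600).
#' @param fs Sampling rate in Hz (default 20). `duration_s * fs` must be an
#'   integer sample count.
#' @param n_cells Number of simulated cells.
#' @param rest_rate,run_rate Event rates in events/min per cell. Non-modulated
#'   cells fire at `rest_rate` throughout; movement-modulated cells fire at
#'   `run_rate` inside running bouts.
#' @param rise_s,decay_s Event-kernel rise time (linear ramp) and decay time
#'   constant (exponential), in seconds.
#' @param amp_mean,amp_sd Event amplitude distribution in dF/F units.
#' @param noise_sd Additive Gaussian noise SD in dF/F units.
#' @param bout_mean_s Mean running-bout duration in seconds.
#' @param n_bouts Number of running bouts per session.
#' @param shared_fraction Probability that a member of a correlated pair copies
#'   each event of the pair's latent source train. Either a scalar or a named
#'   vector `c(rest = , run = )` for state-dependent sharing.
#' @param n_shared_pairs Number of disjoint cell pairs wired to a common latent
#'   source train (pairs `(1,2), (3,4), ...`).
#' @param modulated_fraction Fraction of cells that are movement-modulated.
#' @param seed Integer RNG seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(duration_s = 600, fs = 20, n_cells = 50,
                       rest_rate = 1.71, run_rate = 2.79,
                       rise_s = 0.5, decay_s = 1.0,
                       amp_mean = 0.5, amp_sd = 0.1, noise_sd = 0.02,
                       bout_mean_s = 12, n_bouts = 20,
                       shared_fraction = 0, n_shared_pairs = 0,
                       modulated_fraction = 0.25, seed = 1L) {
  cfg <- list(
    duration_s = duration_s, fs = fs, n_cells = as.integer(n_cells),
    rest_rate = rest_rate, run_rate = run_rate,
    rise_s = rise_s, decay_s = decay_s,
    amp_mean = amp_mean, amp_sd = amp_sd, noise_sd = noise_sd,
    bout_mean_s = bout_mean_s, n_bouts = as.integer(n_bouts),
    shared_fraction = shared_fraction,
    n_shared_pairs = as.integer(n_shared_pairs),
    modulated_fraction = modulated_fraction, seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$fs <= 0) stop("sim_config: `fs` must be positive")
  n <- cfg$duration_s * cfg$fs
  if (abs(n - round(n)) > 1e-8) {
    stop("sim_config: `duration_s * fs` must be an integer sample count")
  }
  if (cfg$rest_rate < 0 || cfg$run_rate < 0) {
    stop("sim_config: event rates must be non-negative")
  }
  sf <- cfg$shared_fraction
  if (any(sf < 0) || any(sf > 1)) {
    stop("sim_config: `shared_fraction` must lie in [0, 1]")
  }
  if (length(sf) > 1L && !all(c("rest", "run") %in% names(sf))) {
    stop("sim_config: a non-scalar `shared_fraction` must be named c(rest=, run=)")
  }
  if (cfg$modulated_fraction < 0 || cfg$modulated_fraction > 1) {
    stop("sim_config: `modulated_fraction` must lie in [0, 1]")
  }
  if (cfg$n_shared_pairs * 2L > cfg$n_cells) {
    stop("sim_config: `n_shared_pairs` requires at least 2 cells per pair")
  }
  if (cfg$rise_s <= 0 || cfg$decay_s <= 0) {
    stop("sim_config: kernel times must be positive")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a treadmill speed trace with known rest/run bout structure
#'
#' Running bouts are placed at random, separated by rest gaps of at least 4 s.
#' Each bout is a smooth-edged plateau (8-18 cm/s) at least 3 s long; rest
#' segments carry small non-negative jitter.
#'
#' @param cfg A `sim_config`.
#' @return A list with `speed` (a [speed_trace()]) and `bouts` (data frame of
#'   planted run intervals: `start`, `end` inclusive sample indices).
#' @export
simulate_speed <- function(cfg) {
  cfg <- validate_sim_config(unclass(cfg))
  with_seed(cfg$seed, {
    n <- round(cfg$duration_s * cfg$fs)
    v <- abs(stats::rnorm(n, 0, 0.15))
    bouts <- data.frame(start = integer(0), end = integer(0))
    if (cfg$n_bouts > 0L) {
      min_bout_s <- 3
      min_gap_s <- 4
      durations <- pmax(min_bout_s,
                        stats::rgamma(cfg$n_bouts, shape = 4,
                                      rate = 4 / cfg$bout_mean_s))
      budget <- cfg$duration_s - sum(durations) - min_gap_s * (cfg$n_bouts + 1L)
      if (budget < 0) {
        # requested bouts do not fit; shrink towards the feasible total
        durations <- durations * (cfg$duration_s * 0.6 / sum(durations))
        durations <- pmax(min_bout_s, durations)
        budget <- cfg$duration_s - sum(durations) - min_gap_s * (cfg$n_bouts + 1L)
        if (budget < 0) stop("simulate_speed: bouts do not fit in the session")
      }
      slack <- stats::rexp(cfg$n_bouts + 1L)
      gaps <- min_gap_s + budget * slack / sum(slack)
      start_s <- cumsum(gaps)[seq_len(cfg$n_bouts)] +
        c(0, cumsum(durations))[seq_len(cfg$n_bouts)]
      for (k in seq_len(cfg$n_bouts)) {
        i0 <- max(1L, round(start_s[k] * cfg$fs) + 1L)
        i1 <- min(n, i0 + round(durations[k] * cfg$fs) - 1L)
        plateau <- stats::runif(1, 8, 18)
        len <- i1 - i0 + 1L
        ramp_n <- min(round(0.5 * cfg$fs), len %/% 4L)
        prof <- rep(1, len)
        if (ramp_n > 0L) {
          edge <- (1 - cos(pi * seq_len(ramp_n) / ramp_n)) / 2
          prof[seq_len(ramp_n)] <- edge
          prof[len - ramp_n + seq_len(ramp_n)] <- rev(edge)
        }
        v[i0:i1] <- plateau * prof + abs(stats::rnorm(len, 0, 0.5))
        bouts <- rbind(bouts, data.frame(start = i0, end = i1))
      }
    }
    list(speed = speed_trace(pmax(v, 0), fs = cfg$fs), bouts = bouts)
  })
}

#' Simulate two-sensor treadmill displacement streams from a speed trace
#'
#' Inverse of [compute_velocity()]: decomposes speed into perpendicular
#' components along a heading profile, then projects onto the two sensor axes
#' an angle `theta` apart, so that feeding the streams back through
#' [compute_velocity()] recovers the input speed to numerical tolerance.
#'
#' @param speed A [speed_trace()].
#' @param theta Sensor separation angle in radians, strictly inside (0, pi).
#' @param heading Heading angle in radians: a scalar, a vector matching the
#'   trace length, or `NULL` for a slow sinusoidal wander.
#' @return A list with numeric vectors `L` and `R` and the `theta` used.
#' @export
simulate_sensors <- function(speed, theta = 78 * pi / 180, heading = NULL) {
  if (theta <= 0 || theta >= pi) {
    stop("simulate_sensors: `theta` must lie strictly inside (0, pi)")
  }
  v <- if (inherits(speed, "speed_trace")) speed$v else as.numeric(speed)
  n <- length(v)
  if (is.null(heading)) {
    t_s <- (seq_len(n) - 1) / attr(speed, "fs")
    heading <- pi / 4 + 0.3 * sin(2 * pi * t_s / 60)
  }
  if (length(heading) == 1L) heading <- rep(heading, n)
  stopifnot(length(heading) == n)
  X <- v * cos(heading)
  Y <- v * sin(heading)
  list(L = X * sin(theta) + Y * cos(theta), R = Y, theta = theta)
}

# Per-sample event-onset probability vector (events/min -> probability).
onset_prob <- function(rate_per_min, fs) rate_per_min / 60 / fs

# Sample onsets of a (possibly inhomogeneous) Bernoulli/Poisson process.
sample_onsets <- function(p) which(stats::runif(length(p)) < p)

# Shared-fraction lookup per sample state ("rest"/"run" indicator).
shared_prob_at <- function(sf, run_mask, idx) {
  if (length(sf) == 1L) return(rep(as.numeric(sf), length(idx)))
  ifelse(run_mask[idx], sf[["run"]], sf[["rest"]])
}

#' Simulate normalized GCaMP-like fluorescence traces with ground truth
#'
#' Each cell emits calcium events as a per-sample Bernoulli (Poisson) process:
#' movement-modulated cells fire at `run_rate` inside running bouts and
#' `rest_rate` elsewhere; non-modulated cells fire at `rest_rate` throughout.
#' Cells in a shared pair additionally copy events from a latent source train
#' (rate `rest_rate`) with probability `shared_fraction`, with their private
#' rate reduced so the total stays at the configured rate. Events are rendered
#' with a linear rise over `rise_s` followed by an exponential decay with time
#' constant `decay_s`, amplitudes drawn from `N(amp_mean, amp_sd)`, Gaussian
#' noise added, and each trace min-max normalized to [0, 1].
#'
#' Cell centroids are laid out on a jittered grid in a 1,024-pixel field of
#' view so that every pair is at least 20 pixels apart.
#'
#' @param cfg A `sim_config`.
#' @param bouts Data frame of planted run intervals (from [simulate_speed()]).
#' @return A list of class `ca_simulation` with elements `traces` (samples x
#'   cells matrix in [0, 1]), `time_s`, `centroids` (data frame `x`, `y` in
#'   pixels), and `truth` (list: per-cell `onsets` and `peaks` sample indices,
#'   logical `modulated`, `shared_pairs` data frame, `bouts`).
#' @export
simulate_traces <- function(cfg, bouts) {
  cfg <- validate_sim_config(unclass(cfg))
  with_seed(cfg$seed + 1L, {
    n <- round(cfg$duration_s * cfg$fs)
    run_mask <- rep(FALSE, n)
    for (k in seq_len(nrow(bouts))) run_mask[bouts$start[k]:bouts$end[k]] <- TRUE

    n_mod <- round(cfg$modulated_fraction * cfg$n_cells)
    modulated <- rep(FALSE, cfg$n_cells)
    if (n_mod > 0L) modulated[sample(cfg$n_cells, n_mod)] <- TRUE

    sf <- cfg$shared_fraction
    shared_pairs <- data.frame(i = integer(0), j = integer(0))
    source_onsets <- list()
    if (cfg$n_shared_pairs > 0L) {
      shared_pairs <- data.frame(
        i = seq(1L, by = 2L, length.out = cfg$n_shared_pairs),
        j = seq(2L, by = 2L, length.out = cfg$n_shared_pairs)
      )
      p_src <- rep(onset_prob(cfg$rest_rate, cfg$fs), n)
      source_onsets <- lapply(seq_len(cfg$n_shared_pairs),
                              function(k) sample_onsets(p_src))
    }

    # cell -> its shared pair row (0 if none)
    pair_of <- integer(cfg$n_cells)
    for (k in seq_len(nrow(shared_pairs))) {
      pair_of[shared_pairs$i[k]] <- k
      pair_of[shared_pairs$j[k]] <- k
    }

    rise_n <- max(1L, round(cfg$rise_s * cfg$fs))
    decay_n <- max(1L, round(6 * cfg$decay_s * cfg$fs))
    kern_rise <- seq_len(rise_n) / rise_n
    kern_decay <- exp(-seq_len(decay_n) / (cfg$decay_s * cfg$fs))
    kernel <- c(0, kern_rise, kern_decay)

    onsets <- vector("list", cfg$n_cells)
    traces <- matrix(0, nrow = n, ncol = cfg$n_cells)
    for (cell in seq_len(cfg$n_cells)) {
      rate <- rep(cfg$rest_rate, n)
      if (modulated[cell]) rate[run_mask] <- cfg$run_rate
      own_rate <- rate
      copied <- integer(0)
      if (pair_of[cell] > 0L) {
        src <- source_onsets[[pair_of[cell]]]
        p_copy <- shared_prob_at(sf, run_mask, src)
        copied <- src[stats::runif(length(src)) < p_copy]
        sf_vec <- if (length(sf) == 1L) rep(as.numeric(sf), n) else {
          ifelse(run_mask, sf[["run"]], sf[["rest"]])
        }
        own_rate <- pmax(0, rate - sf_vec * cfg$rest_rate)
      }
      own <- sample_onsets(onset_prob(own_rate, cfg$fs))
      ons <- sort(unique(c(own, copied)))
      ons <- ons[ons + rise_n <= n]
      onsets[[cell]] <- ons
      sig <- numeric(n)
      if (length(ons)) {
        amps <- pmax(0.1 * cfg$amp_mean,
                     stats::rnorm(length(ons), cfg$amp_mean, cfg$amp_sd))
        for (e in seq_along(ons)) {
          idx <- ons[e] + seq_along(kernel) - 1L
          keep <- idx <= n
          sig[idx[keep]] <- sig[idx[keep]] + amps[e] * kernel[keep]
        }
      }
      sig <- sig + stats::rnorm(n, 0, cfg$noise_sd)
      rng <- range(sig)
      if (diff(rng) < .Machine$double.eps) {
        traces[, cell] <- 0
      } else {
        traces[, cell] <- (sig - rng[1]) / diff(rng)
      }
    }

    centroids <- grid_centroids(cfg$n_cells)
    out <- list(
      traces = traces,
      time_s = (seq_len(n) - 1) / cfg$fs,
      fs = cfg$fs,
      centroids = centroids,
      truth = list(
        onsets = onsets,
        peaks = lapply(onsets, function(o) o + rise_n),
        modulated = modulated,
        shared_pairs = shared_pairs,
        bouts = bouts
      )
    )
    class(out) <- "ca_simulation"
    out
  })
}

# Jittered-grid centroids in a 1024 px field, pairwise distance >= 24 px.
grid_centroids <- function(n_cells, fov_px = 1024, spacing = 40, jitter = 8) {
  per_row <- max(1L, floor((fov_px - 2 * spacing) / spacing))
  ij <- cbind((seq_len(n_cells) - 1L) %% per_row,
              (seq_len(n_cells) - 1L) %/% per_row)
  data.frame(
    x = spacing + ij[, 1] * spacing + stats::runif(n_cells, -jitter, jitter),
    y = spacing + ij[, 2] * spacing + stats::runif(n_cells, -jitter, jitter)
  )
}

#' @export
print.ca_simulation <- function(x, ...) {
  cat(sprintf(
    "Synthetic calcium session: %d cells, %d samples at %g Hz (%.0f s)\n",
    ncol(x$traces), nrow(x$traces), x$fs, nrow(x$traces) / x$fs
  ))
  cat(sprintf("  modulated cells: %d; shared pairs: %d; run bouts: %d\n",
              sum(x$truth$modulated), nrow(x$truth$shared_pairs),
              nrow(x$truth$bouts)))
  invisible(x)
}

#' Simulate a toy fluorescence video with known per-frame shifts
#'
#' A reference scene of 2-D Gaussian "cells" is translated by the given
#' integer per-frame shifts (zero-filled at the edges) and Gaussian noise is
#' added, providing a registration fixture with exact ground truth.
#'
#' @param cfg A `sim_config` (only `n_cells`, `noise_sd`, `seed` are used).
#' @param shifts Integer matrix `n_frames x 2` of per-frame `(dy, dx)` shifts.
#' @param dim Frame dimensions `c(h, w)`.
#' @param margin Maximum allowed absolute shift; also keeps cells away from the
#'   frame edges.
#' @param cell_sigma Gaussian blob SD in pixels.
#' @return A list with `frames` (array `h x w x n_frames`), `reference` (the
#'   unshifted noiseless scene), `shifts`, and `rois` (list with `masks`
#'   logical array and `centroids` data frame, reference coordinates).
#' @export
simulate_video <- function(cfg, shifts, dim = c(64, 64), margin = 8,
                           cell_sigma = 2) {
  cfg <- validate_sim_config(unclass(cfg))
  shifts <- matrix(as.integer(shifts), ncol = 2)
  if (any(abs(shifts) > margin)) {
    stop("simulate_video: shifts exceed the allowed margin")
  }
  if (margin >= min(dim) / 2) stop("simulate_video: margin too large for frame")
  with_seed(cfg$seed + 2L, {
    h <- dim[1]; w <- dim[2]
    n_blobs <- min(cfg$n_cells, 12L)
    cy <- round(stats::runif(n_blobs, margin + 4 * cell_sigma,
                             h - margin - 4 * cell_sigma))
    cx <- round(stats::runif(n_blobs, margin + 4 * cell_sigma,
                             w - margin - 4 * cell_sigma))
    yy <- matrix(seq_len(h), h, w)
    xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    ref <- matrix(0, h, w)
    for (b in seq_len(n_blobs)) {
      ref <- ref + exp(-((yy - cy[b])^2 + (xx - cx[b])^2) / (2 * cell_sigma^2))
    }
    masks <- array(FALSE, c(h, w, n_blobs))
    for (b in seq_len(n_blobs)) {
      masks[, , b] <- (yy - cy[b])^2 + (xx - cx[b])^2 <= (2 * cell_sigma)^2
    }
    n_frames <- nrow(shifts)
    frames <- array(0, c(h, w, n_frames))
    for (f in seq_len(n_frames)) {
      fr <- translate_image(ref, shifts[f, 1], shifts[f, 2])
      frames[, , f] <- fr + stats::rnorm(h * w, 0, cfg$noise_sd)
    }
    list(
      frames = frames, reference = ref, shifts = shifts,
      rois = list(masks = masks, centroids = data.frame(x = cx, y = cy))
    )
  })
}

# Integer translation with zero fill: out[y, x] = img[y - dy, x - dx].
translate_image <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h
  okx <- xs >= 1 & xs <= w
  out[oky, okx] <- img[ys[oky], xs[okx]]
  out
}
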