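test_that("DPSS tapers are orthonormal and band-concentrated", {
  tap <- dpss_tapers(20, nw = 2, k = 3)
  expect_equal(crossprod(tap), diag(3), tolerance = 1e-8)
  # the first taper concentrates its energy below the design bandwidth W
  spec <- Mod(stats::fft(c(tap[, 1], rep(0, 236))))^2
  inband <- sum(spec[1:(ceiling(2 / 20 * 256) + 1)]) / (sum(spec) / 2)
  expect_gt(inband, 0.95)
})

test_that("low-frequency power scales quadratically and peaks at events", {
  # constant trace: power ~ 0 after per-window mean removal
  lp0 <- lowfreq_power(rep(0.4, 400))
  expect_lt(max(lp0$power), 1e-20)
  # doubling the amplitude quadruples the power
  set.seed(1)
  x <- planted_trace(800, onsets = c(200, 500), amp = 0.5)
  p1 <- lowfreq_power(x)$power
  p2 <- lowfreq_power(2 * x)$power
  expect_equal(p2, 4 * p1, tolerance = 1e-8)
  # single planted event: power maximum within +/- 0.5 s of the rise
  x1 <- planted_trace(800, onsets = 400, amp = 0.5)
  lp <- lowfreq_power(x1)
  tmax <- lp$center_idx[which.max(lp$power)]
  expect_lte(abs(tmax - 405), 10)
  expect_error(lowfreq_power(rep(0, 5)), "shorter")
})

test_that("candidate outlier groups match a brute-force scan", {
  # monotone power -> constant diff -> no candidates
  expect_equal(nrow(candidate_events(seq_len(100))), 0L)
  # one step jump -> exactly one candidate group
  step <- c(rep(0, 50), rep(5, 50)) + seq_len(100) * 1e-4
  expect_equal(nrow(candidate_events(step)), 1L)
  # random series: agreement with an independent outlier scan
  set.seed(2)
  for (rep in 1:5) {
    p <- cumsum(rnorm(300)) + c(rep(0, 150), rep(30, 150))
    got <- candidate_events(p)
    pd <- diff(p)
    flag <- abs(pd - median(pd)) > 3 * 1.4826 * median(abs(pd - median(pd)))
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    exp_groups <- data.frame(start = (ends - r$lengths + 1L)[r$values],
                             end = ends[r$values])
    expect_equal(got[, c("start", "end")], exp_groups, ignore_attr = TRUE)
  }
})

test_that("a clean planted event is detected once with an accurate onset", {
  set.seed(3)
  x <- planted_trace(2400, onsets = 1200, amp = 0.5, rise_n = 10,
                     noise_sd = 0.02)
  x <- (x - min(x)) / diff(range(x))
  ev <- detect_events(x)
  expect_equal(nrow(ev), 1L)
  expect_lte(abs(ev$t_on - 1200), 2)
  expect_gte(ev$amplitude, 0.5 / diff(range(x)) * 0.7)
})

test_that("flat and noise-only traces yield no detections", {
  set.seed(4)
  for (rep in 1:3) {
    x <- normalize_trace(rnorm(6000, 0, 0.02))
    expect_equal(nrow(detect_events(x)), 0L)
  }
})

test_that("the detector meets its recovery contract on simulated sessions", {
  cfg <- sim_config(duration_s = 600, n_cells = 4, seed = 31,
                    modulated_fraction = 0.5)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  sens <- c(); errs <- c()
  for (c in 1:4) {
    truth <- sim$truth$onsets[[c]]
    det <- detect_events(sim$traces[, c])
    # detections are ordered and non-overlapping (t_on < t_peak, disjoint)
    expect_true(all(det$t_on < det$t_peak))
    expect_true(all(diff(det$t_on) > 0))
    expect_true(all(det$t_on[-1] > det$t_peak[-nrow(det)]))
    expect_true(all(det$rise_s >= 0.15))
    expect_true(all(det$amplitude > 0))
    matched <- vapply(truth, function(o) any(abs(det$t_on - o) <= 10), logical(1))
    sens <- c(sens, matched)
    errs <- c(errs, vapply(truth[matched], function(o) min(abs(det$t_on - o)),
                           numeric(1)))
  }
  expect_gte(mean(sens), 0.85)
  expect_lte(mean(errs), 2) # <= 100 ms at 20 Hz
})

test_that("event metrics compute FWHM geometry and exclusion rules", {
  # symmetric triangular event, base 2 s, height 1: FWHM = 1 s
  x <- c(rep(0, 100), seq(0, 1, length.out = 21)[-1],
         seq(1, 0, length.out = 21)[-1], rep(0, 100))
  m <- event_metrics(t_on = 100, t_peak = 120, trace = x, fs = 20)
  expect_equal(m$reason, "none")
  expect_equal(m$fwhm_s, 1, tolerance = 0.06)
  # a second event onset inside the FWHM span triggers exclusion
  m2 <- event_metrics(t_on = 100, t_peak = 120, trace = x, fs = 20,
                      next_on = 125)
  expect_equal(m2$reason, "next_event_overlap")
  # two peaks above 75% of the height trigger the multi-peak exclusion
  x3 <- c(rep(0, 100), seq(0, 1, length.out = 11)[-1],
          seq(1, 0.5, length.out = 11)[-1], seq(0.5, 0.95, length.out = 11)[-1],
          seq(0.95, 0, length.out = 21)[-1], rep(0, 100))
  m3 <- event_metrics(t_on = 100, t_peak = 110, trace = x3, fs = 20)
  expect_equal(m3$reason, "multi_peak")
})

test_that("event rates count onsets inside the right state", {
  # 10 events inside 300 s of run time -> 2.0 events/min
  n <- 12000
  bouts <- data.frame(start = c(1001, 7001), end = c(4000, 10000))
  seg <- seg_from_bouts(n, bouts)
  t_run <- state_time(seg, "run")
  run_idx <- state_indices(seg, "run")
  ons <- run_idx[round(seq(1, length(run_idx), length.out = 10))]
  ev <- data.frame(t_on = ons, t_peak = ons + 10)
  expect_equal(event_rate(ev, seg, "run"), 10 / t_run * 60)
  expect_equal(event_rate(ev[0, ], seg, "run"), 0)
  expect_equal(event_rate(ev, n_samples = n, fs = 20), 10 / 600 * 60)
  expect_error(event_rate(ev, seg_from_bouts(n, bouts[0, ]), "run"), "no time")
})

test_that("state-conditioned rates recover the planted rest/run rates", {
  cfg <- sim_config(duration_s = 600, n_cells = 30, rest_rate = 1.7,
                    run_rate = 2.8, modulated_fraction = 1, seed = 13)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  seg <- seg_from_bouts(nrow(sim$traces), sp$bouts)
  rates <- vapply(c("rest", "run"), function(st) {
    mean(vapply(seq_len(30), function(c) {
      ev <- data.frame(t_on = sim$truth$onsets[[c]],
                       t_peak = sim$truth$peaks[[c]])
      event_rate(ev, seg, st)
    }, numeric(1)))
  }, numeric(1))
  # within 3 SE of the Poisson expectation (SE on the pooled cell mean)
  t_rest <- state_time(seg, "rest") / 60; t_run <- state_time(seg, "run") / 60
  se_rest <- sqrt(1.7 / (t_rest * 30)); se_run <- sqrt(2.8 / (t_run * 30))
  expect_lt(abs(rates[["rest"]] - 1.7), 3 * se_rest)
  expect_lt(abs(rates[["run"]] - 2.8), 3 * se_run)
})
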