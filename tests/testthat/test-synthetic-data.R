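test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(fs = -1), "fs")
  expect_error(sim_config(duration_s = 10.03), "integer sample count")
  expect_error(sim_config(rest_rate = -1), "rates")
  expect_error(sim_config(shared_fraction = 1.5), "shared_fraction")
  expect_error(sim_config(modulated_fraction = 2), "modulated_fraction")
  expect_error(sim_config(n_cells = 3, n_shared_pairs = 2), "n_shared_pairs")
})

test_that("simulated speed has the requested bout structure", {
  cfg0 <- sim_config(duration_s = 60, n_bouts = 0, seed = 1)
  sp0 <- simulate_speed(cfg0)
  expect_lt(max(sp0$speed$v), 2)
  expect_equal(nrow(sp0$bouts), 0L)

  cfg <- sim_config(duration_s = 300, n_bouts = 5, bout_mean_s = 10, seed = 2)
  sp <- simulate_speed(cfg)
  expect_equal(nrow(sp$bouts), 5L)
  expect_true(all(sp$speed$v >= 0))
  expect_true(all(sp$bouts$end - sp$bouts$start + 1 >= 2 * 20))
  expect_true(all(sp$bouts$start[-1] > sp$bouts$end[-5])) # disjoint, ordered
  for (k in 1:5) {
    expect_gte(mean(sp$speed$v[sp$bouts$start[k]:sp$bouts$end[k]]), 5)
  }
})

test_that("identical config and seed give bit-identical simulations", {
  cfg <- sim_config(duration_s = 60, n_cells = 4, n_bouts = 3, seed = 7,
                    n_shared_pairs = 1, shared_fraction = 0.5)
  a1 <- simulate_speed(cfg); a2 <- simulate_speed(cfg)
  expect_identical(a1, a2)
  t1 <- simulate_traces(cfg, a1$bouts); t2 <- simulate_traces(cfg, a2$bouts)
  expect_identical(t1, t2)
})

test_that("sensor simulation round-trips through compute_velocity", {
  cfg <- sim_config(duration_s = 120, n_bouts = 4, seed = 3)
  sp <- simulate_speed(cfg)
  # orthogonal sensors, constant speed
  sn90 <- simulate_sensors(speed_trace(rep(10, 100)), theta = pi / 2,
                           heading = 0.7)
  v90 <- compute_velocity(sn90$L, sn90$R, theta = pi / 2)
  expect_lt(max(abs(v90$v - 10)), 1e-9)
  # 78-degree sensors, arbitrary wandering heading
  sn <- simulate_sensors(sp$speed, theta = 78 * pi / 180)
  v <- compute_velocity(sn$L, sn$R, theta = sn$theta)
  expect_lt(max(abs(v$v - sp$speed$v)), 1e-6)
  # zero speed gives zero streams
  sn0 <- simulate_sensors(speed_trace(rep(0, 50)), theta = 1.2)
  expect_equal(sn0$L, rep(0, 50))
  expect_equal(sn0$R, rep(0, 50))
  expect_error(simulate_sensors(sp$speed, theta = 0), "theta")
})

test_that("a noiseless planted event reproduces the pure kernel shape", {
  cfg <- sim_config(duration_s = 30, n_cells = 1, noise_sd = 0,
                    rest_rate = 2, run_rate = 2, n_bouts = 0,
                    modulated_fraction = 0, seed = 11)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  ons <- sim$truth$onsets[[1]]
  # traces normalized to [0, 1]
  expect_equal(min(sim$traces[, 1]), 0)
  expect_equal(max(sim$traces[, 1]), 1)
  if (length(ons) == 1) {
    expect_equal(which.max(sim$traces[, 1]), sim$truth$peaks[[1]][1])
  }
})

test_that("equal rest and run rates produce no modulated labels", {
  cfg <- sim_config(duration_s = 60, n_cells = 6, rest_rate = 2, run_rate = 2,
                    n_bouts = 2, bout_mean_s = 8, modulated_fraction = 0,
                    seed = 4)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  expect_false(any(sim$truth$modulated))
})

test_that("realized event counts match the configured Poisson rates", {
  # 200 cells, 600 s, rest 1.7 / run 2.8 events/min: total expected counts
  # within 3 SD of the Poisson expectation
  cfg <- sim_config(duration_s = 600, n_cells = 200, rest_rate = 1.7,
                    run_rate = 2.8, modulated_fraction = 1, seed = 12)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  run_mask <- rep(FALSE, nrow(sim$traces))
  for (k in seq_len(nrow(sp$bouts))) {
    run_mask[sp$bouts$start[k]:sp$bouts$end[k]] <- TRUE
  }
  t_run_min <- sum(run_mask) / 20 / 60
  t_rest_min <- sum(!run_mask) / 20 / 60
  n_run <- sum(vapply(sim$truth$onsets, function(o) sum(run_mask[o]), numeric(1)))
  n_rest <- sum(vapply(sim$truth$onsets, function(o) sum(!run_mask[o]), numeric(1)))
  exp_run <- 2.8 * t_run_min * 200
  exp_rest <- 1.7 * t_rest_min * 200
  expect_lt(abs(n_run - exp_run), 3 * sqrt(exp_run))
  expect_lt(abs(n_rest - exp_rest), 3 * sqrt(exp_rest))
})

test_that("shared-source pairs are more correlated as shared_fraction grows", {
  mean_r_at <- function(sf, seed) {
    cfg <- sim_config(duration_s = 600, n_cells = 20, n_shared_pairs = 10,
                      shared_fraction = sf, rise_s = 1.0,
                      modulated_fraction = 0, seed = seed)
    sp <- simulate_speed(cfg)
    sim <- simulate_traces(cfg, sp$bouts)
    n <- nrow(sim$traces)
    mean(vapply(seq_len(10), function(k) {
      xi <- binarize(data.frame(t_on = sim$truth$onsets[[2 * k - 1]],
                                t_peak = sim$truth$peaks[[2 * k - 1]]), n)
      xj <- binarize(data.frame(t_on = sim$truth$onsets[[2 * k]],
                                t_peak = sim$truth$peaks[[2 * k]]), n)
      suppressWarnings(stats::cor(xi, xj))
    }, numeric(1)), na.rm = TRUE)
  }
  r0 <- mean(vapply(1:3, function(s) mean_r_at(0, s), numeric(1)))
  r5 <- mean(vapply(1:3, function(s) mean_r_at(0.5, s), numeric(1)))
  r9 <- mean(vapply(1:3, function(s) mean_r_at(0.9, s), numeric(1)))
  expect_gt(r5, r0)
  expect_gt(r9, r5)
})

test_that("simulated video frames carry the planted integer shifts", {
  cfg <- sim_config(n_cells = 8, noise_sd = 0, seed = 6)
  shifts <- rbind(c(0, 0), c(3, -2), c(-5, 4))
  vid <- simulate_video(cfg, shifts, dim = c(48, 48))
  # all-zero shift frame equals the reference exactly (no noise)
  expect_equal(vid$frames[, , 1], vid$reference)
  # planted shift: frame equals the translated reference
  expect_equal(vid$frames[, , 2],
               ca1net:::translate_image(vid$reference, 3, -2))
  expect_error(simulate_video(cfg, rbind(c(30, 0)), dim = c(48, 48)),
               "margin")
})
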