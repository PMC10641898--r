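test_that("pair eligibility applies the 20-pixel rule at its boundary", {
  expect_false(pair_eligible(c(0, 0), c(19.9, 0)))
  expect_true(pair_eligible(c(0, 0), c(20, 0))) # "at least" 20 px
  expect_true(pair_eligible(c(0, 0), c(15, 15)))
  # 20 px at the 1.343 mm / 1024 px field of view is 26.2 um
  expect_equal(round(px_to_um(20), 1), 26.2)
})

test_that("state concatenation selects exactly the in-state samples", {
  n <- 1000
  seg <- seg_from_bouts(n, data.frame(start = c(101, 501), end = c(200, 600)))
  x <- seq_len(n)
  expect_equal(state_concatenate(x, seg, "session"), x)
  run_idx <- state_indices(seg, "run")
  expect_equal(state_concatenate(x, seg, "run"), x[run_idx])
  # event recount: onsets inside bouts survive concatenation
  set.seed(1)
  tr <- random_train(n, 40, rise_n = 4)
  expect_equal(sum(state_concatenate(tr, seg, "run")), sum(tr[run_idx]))
})

test_that("all-lag binary correlations equal direct Pearson on rotations", {
  set.seed(2)
  n <- 600
  xi <- random_train(n, 40, rise_n = 6)
  xj <- random_train(n, 60, rise_n = 6)
  r_all <- ca1net:::binary_r_all_lags(xi = as.numeric(xi), xj = as.numeric(xj),
                                      s1 = sum(xi), s2 = sum(xj), L = n)
  for (m in c(0, 1, 50, 311, 599)) {
    expect_equal(r_all[m + 1], stats::cor(xi, rot(xj, m)), tolerance = 1e-9)
  }
})

test_that("correlation test classifies identical, shared and constant trains", {
  set.seed(3)
  n <- 6000
  x <- random_train(n, 15, rise_n = 10)
  r_id <- correlation_test(x, x, n_shuffles = 500, seed = 1)
  expect_equal(r_id$r, 1)
  expect_equal(r_id$klass, "correlated")
  expect_equal(correlation_test(integer(n), x, seed = 1)$klass, "ineligible")
  # swapping the arguments leaves r unchanged
  y <- random_train(n, 15, rise_n = 10)
  expect_equal(correlation_test(x, y, seed = 2)$r,
               correlation_test(y, x, seed = 2)$r)
})

test_that("classify_session returns a full pair table with sane fractions", {
  cfg <- sim_config(duration_s = 300, n_cells = 8, n_shared_pairs = 2,
                    shared_fraction = 0.9, rise_s = 1.0,
                    modulated_fraction = 0, seed = 21)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  n <- nrow(sim$traces)
  trains <- vapply(seq_len(8), function(c) {
    binarize(data.frame(t_on = sim$truth$onsets[[c]],
                        t_peak = sim$truth$peaks[[c]]), n)
  }, integer(n))
  seg <- seg_from_bouts(n, sp$bouts)
  pr <- classify_session(trains, seg, scope = "session",
                         centroids = sim$centroids, n_shuffles = 500, seed = 5)
  expect_equal(nrow(pr), choose(8, 2))
  expect_true(all(pr$klass %in% c("correlated", "random", "negative_excluded",
                                  "ineligible")))
  # the two planted shared pairs should be among the correlated ones
  planted <- sim$truth$shared_pairs
  for (k in seq_len(nrow(planted))) {
    row <- pr$i == planted$i[k] & pr$j == planted$j[k]
    expect_equal(pr$klass[row], "correlated")
  }
  # classification is deterministic under a fixed seed
  pr2 <- classify_session(trains, seg, scope = "session",
                          centroids = sim$centroids, n_shuffles = 500, seed = 5)
  expect_identical(as.data.frame(pr), as.data.frame(pr2))
  # correlated implies r > 0 and r > null p95
  cc <- pr[pr$klass == "correlated", ]
  expect_true(all(cc$r > 0 & cc$r > cc$null_p95))
})

test_that("subgroup means partition pairs and find planted run effects", {
  cfg <- sim_config(duration_s = 600, n_cells = 10, n_shared_pairs = 2,
                    shared_fraction = c(rest = 0.1, run = 0.9), rise_s = 1.0,
                    modulated_fraction = 0, seed = 22)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  n <- nrow(sim$traces)
  trains <- vapply(seq_len(10), function(c) {
    binarize(data.frame(t_on = sim$truth$onsets[[c]],
                        t_peak = sim$truth$peaks[[c]]), n)
  }, integer(n))
  seg <- seg_from_bouts(n, sp$bouts)
  pr <- classify_session(trains, seg, scope = "session",
                         centroids = sim$centroids, n_shuffles = 500, seed = 6)
  # call the shared-pair members "modulated" so planted pairs are Mod-Mod
  modulated <- seq_len(10) %in% c(sim$truth$shared_pairs$i,
                                  sim$truth$shared_pairs$j)
  sg <- subgroup_means(pr, trains, seg, modulated)
  expect_equal(nrow(sg), 6L)
  expect_equal(sum(sg$n_pairs[sg$state == "rest"]),
               sum(pr$klass == "correlated"))
  mm_run <- sg$mean_r[sg$subgroup == "Mod-Mod" & sg$state == "run"]
  mm_rest <- sg$mean_r[sg$subgroup == "Mod-Mod" & sg$state == "rest"]
  if (sg$n_pairs[sg$subgroup == "Mod-Mod" & sg$state == "run"] > 0) {
    expect_gt(mm_run, mm_rest)
  }
  # all cells modulated: only Mod-Mod is populated
  sg_all <- subgroup_means(pr, trains, seg, rep(TRUE, 10))
  expect_true(all(sg_all$n_pairs[sg_all$subgroup != "Mod-Mod"] == 0))
})

test_that("circular shuffles destroy temporal structure in the rate control", {
  cfg <- sim_config(duration_s = 600, n_cells = 8, n_shared_pairs = 4,
                    shared_fraction = 1, rise_s = 1.0,
                    modulated_fraction = 0, seed = 23)
  sp <- simulate_speed(cfg)
  sim <- simulate_traces(cfg, sp$bouts)
  n <- nrow(sim$traces)
  trains <- vapply(seq_len(8), function(c) {
    binarize(data.frame(t_on = sim$truth$onsets[[c]],
                        t_peak = sim$truth$peaks[[c]]), n)
  }, integer(n))
  seg <- seg_from_bouts(n, sp$bouts)
  rc <- rate_correlation_control(trains, seg, scope = "rest",
                                 n_shuffles = 100, seed = 7)
  expect_equal(nrow(rc), choose(8, 2) * 100)
  # even perfectly shared pairs have shuffled r near zero on average
  expect_lt(abs(mean(rc$r_shuffled)), 0.01)
  expect_true(all(rc$mean_rate_ev_min >= 0))
})
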