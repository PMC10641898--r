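test_that("the registration reference is the mean of leading frames", {
  set.seed(1)
  frames <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  ref <- build_reference(frames)
  expect_equal(ref, apply(frames, c(1, 2), mean))
  # identical frames reproduce any frame; constant frames average exactly
  same <- array(rep(frames[, , 1], 4), c(16, 16, 4))
  expect_equal(build_reference(same), frames[, , 1])
  two <- array(c(matrix(0, 4, 4), matrix(2, 4, 4)), c(4, 4, 2))
  expect_equal(build_reference(two), matrix(1, 4, 4))
  # only the first n_ref frames enter
  expect_equal(build_reference(frames, n_ref = 2),
               apply(frames[, , 1:2], c(1, 2), mean))
})

test_that("image enhancement z-normalizes and rejects flat images", {
  set.seed(2)
  img <- matrix(rnorm(64 * 64), 64) + outer(1:64, 1:64, function(i, j) i / 10)
  enh <- enhance_image(img)
  expect_equal(mean(enh), 0, tolerance = 1e-10)
  expect_equal(stats::sd(enh), 1, tolerance = 1e-10)
  expect_error(enhance_image(matrix(3, 32, 32)), "zero variance")
})

test_that("enhancement is translation-equivariant away from borders", {
  cfg <- sim_config(n_cells = 8, noise_sd = 0, seed = 3)
  vid <- simulate_video(cfg, rbind(c(0, 0)), dim = c(64, 64))
  img <- vid$reference
  sh <- ca1net:::translate_image(img, 2, 3)
  a <- ca1net:::translate_image(enhance_image(img), 2, 3)
  b <- enhance_image(sh)
  core <- 20:44
  expect_lt(max(abs(a[core, core] - b[core, core])), 0.05 * diff(range(a)))
})

test_that("registration recovers known integer shifts exactly without noise", {
  cfg <- sim_config(n_cells = 8, noise_sd = 0, seed = 4)
  shifts <- rbind(c(0, 0), c(3, -2), c(-4, 5), c(6, 6), c(-6, -1))
  vid <- simulate_video(cfg, shifts, dim = c(64, 64))
  ref_enh <- enhance_image(vid$reference)
  for (f in seq_len(nrow(shifts))) {
    est <- register_frame(ref_enh, enhance_image(vid$frames[, , f]))
    expect_equal(unname(est), unname(shifts[f, ]))
  }
})

test_that("registration recovers at least 95% of random shifts under noise", {
  cfg <- sim_config(n_cells = 10, noise_sd = 0.02, seed = 5)
  set.seed(5)
  n_frames <- 100
  shifts <- cbind(sample(-5:5, n_frames, TRUE), sample(-5:5, n_frames, TRUE))
  vid <- simulate_video(cfg, shifts, dim = c(64, 64))
  ref_enh <- enhance_image(vid$reference)
  hits <- vapply(seq_len(n_frames), function(f) {
    est <- register_frame(ref_enh, enhance_image(vid$frames[, , f]))
    all(est == shifts[f, ])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("ring background subtraction cancels uniform backgrounds exactly", {
  h <- 120; w <- 120; nf <- 8
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  roi <- (yy - 60)^2 + (xx - 60)^2 <= 36
  set.seed(6)
  bg_t <- runif(nf, 0, 5) # spatially uniform, temporally varying background
  sig <- seq(0.1, 0.8, length.out = nf)
  frames <- array(0, c(h, w, nf))
  for (f in seq_len(nf)) {
    frames[, , f] <- bg_t[f] + sig[f] * roi
  }
  tr <- extract_trace(frames, roi, all_rois = roi)
  expect_false(attr(tr, "flagged"))
  expect_equal(as.numeric(tr), sig, tolerance = 1e-12)
})

test_that("ring excludes other ROIs and flags an empty ring", {
  h <- 120; w <- 120; nf <- 3
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  roi <- (yy - 60)^2 + (xx - 60)^2 <= 25
  other <- (yy - 60)^2 + (xx - 85)^2 <= 100 # inside the ring
  frames <- array(1, c(h, w, nf))
  for (f in seq_len(nf)) {
    fr <- matrix(1, h, w)
    fr[other] <- 50 # would poison the background if not excluded
    fr[roi] <- 3
    frames[, , f] <- fr
  }
  tr <- extract_trace(frames, roi, all_rois = roi | other)
  expect_equal(as.numeric(tr), rep(2, nf)) # 3 - background 1
  # tiny frame: all ring pixels fall in the border exclusion
  small <- array(1, c(40, 40, 2))
  roi_s <- matrix(FALSE, 40, 40); roi_s[19:21, 19:21] <- TRUE
  tr_s <- extract_trace(small, roi_s)
  expect_true(attr(tr_s, "flagged"))
})

test_that("trace normalization detrends, rescales and rejects constants", {
  # pure ramp detrends to a constant and is rejected
  expect_error(normalize_trace(seq(0, 1, length.out = 100)), "constant")
  # ramp plus one event: baseline flattens, event survives
  set.seed(7)
  ev <- planted_trace(400, onsets = 200, amp = 1, noise_sd = 0)
  y <- normalize_trace(ev + seq(0, 0.5, length.out = 400) + rnorm(400, 0, 0.01))
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  expect_equal(which.max(y), 210, tolerance = 2)
  baseline <- y[1:150]
  expect_lt(abs(mean(baseline) - mean(y[300:400])), 0.15)
  # resampling: 10 Hz input interpolated to 20 Hz doubles the length
  y2 <- normalize_trace(seq_len(50) + rnorm(50), fs_in = 10, fs_target = 20)
  expect_equal(length(y2), 99)
})
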