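#' Build the registration reference image
#'
#' Pixelwise mean of the first `min(2047, N)` frames of the stack.
#'
#' @param frames Array `h x w x n_frames`.
#' @param n_ref Maximum number of leading frames to average (default 2047).
#' @return A `h x w` matrix.
#' @export
build_reference <- function(frames, n_ref = 2047L) {
  d <- dim(frames)
  if (length(d) != 3L || d[3] < 1L) stop("`frames` must be a non-empty h x w x n array")
  n0 <- min(n_ref, d[3])
  m <- matrix(frames[, , seq_len(n0)], nrow = d[1] * d[2], ncol = n0)
  matrix(rowMeans(m), d[1], d[2])
}

# Gaussian blur with replicate boundary; brush capped to the image size.
gaussian_blur <- function(img, sigma) {
  radius <- 2L * ceiling(3 * sigma) + 1L
  cap <- min(dim(img))
  if (cap %% 2L == 0L) cap <- cap - 1L
  radius <- min(radius, cap)
  as.matrix(EBImage::gblur(img, sigma = sigma, radius = radius,
                           boundary = "replicate"))
}

#' Contrast-enhance an image for registration
#'
#' Removes the low-frequency background (Gaussian blur, `sigma_bg` px),
#' extracts edges as the difference of two Gaussian-filtered copies
#' (`sigma_hi` and `sigma_lo` px) of the background-removed image, adds the
#' edges back with gain `edge_gain`, and z-normalizes the result (zero mean,
#' unit SD) to guard against overall intensity drift such as photobleaching.
#'
#' @param img 2-D numeric matrix.
#' @param sigma_bg,sigma_hi,sigma_lo Gaussian SDs in pixels (defaults 50, 2, 1).
#' @param edge_gain Multiplier applied to the edge image (default 100).
#' @return Enhanced matrix with mean 0 and SD 1.
#' @export
enhance_image <- function(img, sigma_bg = 50, sigma_hi = 2, sigma_lo = 1,
                          edge_gain = 100) {
  stopifnot(is.matrix(img))
  d <- img - gaussian_blur(img, sigma_bg)
  g_hi <- gaussian_blur(d, sigma_hi)
  g_lo <- gaussian_blur(d, sigma_lo)
  out <- g_hi + edge_gain * (g_hi - g_lo)
  s <- stats::sd(out)
  # tolerance absorbs FFT round-off on constant inputs
  if (!is.finite(s) || s <= 1e-8 * max(1, abs(mean(img)))) {
    stop("enhance_image: image has zero variance")
  }
  (out - mean(out)) / s
}

#' Estimate the integer shift between an enhanced reference and frame
#'
#' FFT cross-correlation of the mean-subtracted, zero-padded images; the peak
#' gives the integer `(dy, dx)` such that `frame[y, x] ~ ref[y - dy, x - dx]`.
#' The corrective shift to apply to the original frame is the negation.
#'
#' @param ref_enh,frame_enh Enhanced images of identical dimensions.
#' @return Integer vector `c(dy, dx)`.
#' @export
register_frame <- function(ref_enh, frame_enh) {
  stopifnot(all(dim(ref_enh) == dim(frame_enh)))
  h <- nrow(ref_enh); w <- ncol(ref_enh)
  A <- matrix(0, 2 * h, 2 * w)
  B <- matrix(0, 2 * h, 2 * w)
  A[seq_len(h), seq_len(w)] <- frame_enh - mean(frame_enh)
  B[seq_len(h), seq_len(w)] <- ref_enh - mean(ref_enh)
  cc <- Re(stats::fft(stats::fft(A) * Conj(stats::fft(B)), inverse = TRUE))
  peak <- arrayInd(which.max(cc), dim(cc))
  lag <- peak - 1L
  dy <- if (lag[1] > h) lag[1] - 2L * h else lag[1]
  dx <- if (lag[2] > w) lag[2] - 2L * w else lag[2]
  c(dy = as.integer(dy), dx = as.integer(dx))
}

#' Rigid motion correction of a fluorescence video stack
#'
#' Builds the reference ([build_reference()]), enhances reference and frames
#' ([enhance_image()]), estimates each frame's integer displacement by FFT
#' cross-correlation ([register_frame()]) and applies the opposite shift to the
#' original frame.
#'
#' @param frames Array `h x w x n_frames`.
#' @param ... Passed to [enhance_image()].
#' @return A list with `corrected` (array like `frames`), `shifts` (data frame
#'   `frame`, `dy`, `dx`), and `reference`.
#' @export
motion_correct <- function(frames, ...) {
  ref <- build_reference(frames)
  ref_enh <- enhance_image(ref, ...)
  n_frames <- dim(frames)[3]
  shifts <- matrix(0L, n_frames, 2)
  corrected <- frames
  for (f in seq_len(n_frames)) {
    s <- register_frame(ref_enh, enhance_image(frames[, , f], ...))
    shifts[f, ] <- s
    corrected[, , f] <- translate_image(frames[, , f], -s[1], -s[2])
  }
  list(
    corrected = corrected,
    shifts = data.frame(frame = seq_len(n_frames),
                        dy = shifts[, 1], dx = shifts[, 2]),
    reference = ref
  )
}

#' Extract a background-subtracted fluorescence trace for one ROI
#'
#' The raw trace is the per-frame mean over the ROI pixels minus the per-frame
#' mean over a background ring centered at the ROI centroid (inner radius 15,
#' outer radius 50 pixels). Pixels belonging to any ROI, and a 25-pixel border
#' along every image edge, are excluded from the ring.
#'
#' @param frames Array `h x w x n_frames`.
#' @param roi Logical `h x w` mask of the target cell.
#' @param all_rois Logical `h x w` mask covering every cell ROI (including the
#'   target), or `NULL` for none.
#' @param inner_r,outer_r Ring radii in pixels.
#' @param border Border exclusion width in pixels.
#' @return Numeric trace of length `n_frames`; attribute `flagged` is `TRUE`
#'   (and no background is subtracted) when the ring is empty after exclusions.
#' @export
extract_trace <- function(frames, roi, all_rois = NULL,
                          inner_r = 15, outer_r = 50, border = 25) {
  d <- dim(frames)
  h <- d[1]; w <- d[2]
  stopifnot(all(dim(roi) == c(h, w)))
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cy <- mean(yy[roi]); cx <- mean(xx[roi])
  r2 <- (yy - cy)^2 + (xx - cx)^2
  ring <- r2 > inner_r^2 & r2 <= outer_r^2
  if (!is.null(all_rois)) ring <- ring & !all_rois
  ring[yy <= border | yy > h - border | xx <= border | xx > w - border] <- FALSE

  m <- matrix(frames, nrow = h * w, ncol = d[3])
  tr <- colMeans(m[which(roi), , drop = FALSE])
  flagged <- !any(ring)
  if (!flagged) tr <- tr - colMeans(m[which(ring), , drop = FALSE])
  attr(tr, "flagged") <- flagged
  tr
}

#' Normalize a raw fluorescence trace
#'
#' Linear interpolation onto a uniform 20 Hz grid, removal of the best-fit
#' line (linear detrend), and min-max scaling to [0, 1].
#'
#' @param raw Numeric trace.
#' @param fs_in Input sampling rate in Hz.
#' @param fs_target Output sampling rate in Hz (default 20).
#' @return Normalized trace with `min = 0`, `max = 1`.
#' @export
normalize_trace <- function(raw, fs_in = 20, fs_target = 20) {
  if (length(raw) < 2L) stop("normalize_trace: need at least 2 samples")
  y <- as.numeric(raw)
  if (fs_in != fs_target) {
    t_in <- (seq_along(y) - 1) / fs_in
    t_out <- seq(0, t_in[length(t_in)], by = 1 / fs_target)
    y <- stats::approx(t_in, y, xout = t_out, rule = 2)$y
  }
  t_idx <- seq_along(y)
  y <- unname(y - stats::fitted(stats::lm(y ~ t_idx)))
  rng <- range(y)
  if (diff(rng) < .Machine$double.eps^0.5 * max(1, abs(rng[2]))) {
    stop("normalize_trace: trace is constant after detrending")
  }
  (y - rng[1]) / diff(rng)
}
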