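#' Write a trace table (time plus one column per cell) as delimited text
#'
#' @param traces `n_samples x n_cells` matrix of normalized dF/F.
#' @param time_s Time stamps in seconds.
#' @param path Output path (tab-separated).
#' @export
write_trace_table <- function(traces, time_s, path) {
  df <- data.frame(time_s = time_s, traces)
  names(df) <- c("time_s", sprintf("cell_%d", seq_len(ncol(traces)) - 1L))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trace table written by [write_trace_table()]
#'
#' @param path Input path.
#' @return List with `traces` matrix and `time_s`.
#' @export
read_trace_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  list(time_s = df$time_s,
       traces = as.matrix(df[, -1, drop = FALSE]))
}

#' Write a bout table (start_s, end_s, label) as delimited text
#'
#' @param seg A [segment_bouts()] result.
#' @param path Output path.
#' @export
write_bout_table <- function(seg, path) {
  iv <- seg$intervals
  df <- data.frame(start_s = (iv$start - 1) / seg$fs,
                   end_s = iv$end / seg$fs,
                   label = iv$label)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a two-sensor displacement table (t, L, R)
#'
#' @param path Input path (tab- or whitespace-separated with header).
#' @return Data frame with columns `t`, `L`, `R`.
#' @export
read_sensor_table <- function(path) {
  df <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("t", "L", "R") %in% names(df)))
  df
}

#' Write a video stack as a multi-page TIFF
#'
#' Pixel values are rescaled to [0, 1] for storage; the scale is not
#' preserved.
#'
#' @param frames Array `h x w x n_frames`.
#' @param path Output path.
#' @export
write_video_tiff <- function(frames, path) {
  rng <- range(frames)
  sc <- if (diff(rng) > 0) (frames - rng[1]) / diff(rng) else frames * 0
  pages <- lapply(seq_len(dim(frames)[3]), function(f) sc[, , f])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a multi-page TIFF as a video stack
#'
#' @param path Input path.
#' @return Array `h x w x n_frames`.
#' @export
read_video_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  array(unlist(pages), c(dim(pages[[1]]), length(pages)))
}
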