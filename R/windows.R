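#' Windowing configuration
#'
#' @param window_seconds Window length in seconds (default 1).
#' @param overlap_fraction Fractional overlap between consecutive windows,
#'   in `[0, 1)` (default 0, i.e. non-overlapping windows).
#' @return An object of class `windowing_config`.
#' @export
windowing_config <- function(window_seconds = 1.0, overlap_fraction = 0.0) {
  if (window_seconds <= 0) stop("window_seconds must be > 0")
  if (overlap_fraction < 0 || overlap_fraction >= 1) {
    stop("overlap_fraction must lie in [0, 1)")
  }
  structure(list(window_seconds = window_seconds,
                 overlap_fraction = overlap_fraction),
            class = "windowing_config")
}

#' Slice a channel into sliding windows
#'
#' Consecutive windows of `window_seconds * fs` samples with hop
#' `window * (1 - overlap)`; a trailing partial window is discarded.
#'
#' @param channel Numeric sample vector.
#' @param fs Sampling rate in Hz.
#' @param cfg A [windowing_config()].
#' @return List with `windows` (list of numeric vectors), `starts`
#'   (0-based start sample of each window) and `times` (start time of each
#'   window in seconds).
#' @export
window_signal <- function(channel, fs, cfg = windowing_config()) {
  w <- cfg$window_seconds * fs
  if (abs(w - round(w)) > 1e-9) {
    stop("window_seconds * fs must be an integer number of samples")
  }
  w <- as.integer(round(w))
  if (w < 8) stop("window must contain at least 8 samples")
  n <- length(channel)
  if (n < w) stop("signal shorter than one window")
  hop <- max(1L, as.integer(round(w * (1 - cfg$overlap_fraction))))
  k <- (n - w) %/% hop + 1L
  starts <- (seq_len(k) - 1L) * hop
  list(
    windows = lapply(starts, function(s) channel[(s + 1):(s + w)]),
    starts = starts,
    times = starts / fs
  )
}
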