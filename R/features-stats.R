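#' Basic statistical features of one window
#'
#' Twelve amplitude-domain descriptors: min, max, mean, RMS, population
#' variance and standard deviation, crest factor (`max|x| / rms`),
#' population skewness and (non-excess) kurtosis, and the 25th/50th/75th
#' percentiles (linear interpolation). Crest factor, skewness and kurtosis
#' of a zero-variance window are defined as 0.
#'
#' @param window Numeric sample vector (length >= 2).
#' @return Named numeric vector of length 12.
#' @export
basic_stat_features <- function(window) {
  n <- length(window)
  if (n < 2) stop("window must have at least 2 samples")
  mu <- mean(window)
  v <- mean((window - mu)^2)
  s <- sqrt(v)
  rms <- sqrt(mean(window^2))
  qs <- unname(quantile(window, c(0.25, 0.5, 0.75), type = 7))
  if (v == 0) {
    crest <- 0; skew <- 0; kurt <- 0
  } else {
    crest <- max(abs(window)) / rms
    skew <- mean((window - mu)^3) / s^3
    kurt <- mean((window - mu)^4) / v^2
  }
  c(min = min(window), max = max(window), mean = mu, rms = rms,
    variance = v, std = s, crest_factor = crest,
    skewness = skew, kurtosis = kurt,
    p25 = qs[1], p50 = qs[2], p75 = qs[3])
}
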