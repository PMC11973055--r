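#' Power spectral density features of one window
#'
#' Eleven metrics from the one-sided periodogram `|X(f)|^2 / (fs N)`,
#' evaluated on the DFT grid restricted to the configured frequency range
#' (1-40 Hz by default; exactly 1 Hz resolution for a 1-s window at 256 Hz):
#' total power, PSD peak and peak-to-peak, power in the delta/theta/alpha/
#' beta/gamma bands, and the slowing ratios
#' `r1 = delta / (alpha + beta)`, `r2 = theta / (alpha + beta)`,
#' `r3 = (delta + theta) / (alpha + beta)`. Bands are half-open
#' `[low, high)` except gamma, which includes its 40 Hz upper edge, so the
#' five band powers partition the total exactly.
#'
#' @param window Numeric sample vector (length >= 2).
#' @param fs Sampling rate in Hz.
#' @param params A [feature_params()].
#' @return Named numeric vector of length 11.
#' @export
psd_features <- function(window, fs, params = feature_params()) {
  if (length(window) < 2) stop("window must have at least 2 samples")
  pg <- periodogram_psd(window, fs)
  lo <- params$freq_range[1]; hi <- params$freq_range[2]
  inr <- pg$freq >= lo & pg$freq <= hi
  bp <- function(band, closed_top = FALSE) {
    m <- if (closed_top) pg$freq >= band[1] & pg$freq <= band[2]
         else pg$freq >= band[1] & pg$freq < band[2]
    sum(pg$psd[m & inr]) * pg$df
  }
  bands <- params$band_edges
  nb <- names(bands)
  pw <- vapply(seq_along(bands),
               function(i) bp(bands[[i]], closed_top = (i == length(bands))), 0)
  names(pw) <- nb
  total <- sum(pg$psd[inr]) * pg$df
  denom <- pw[["alpha"]] + pw[["beta"]]
  ratio <- function(num) {
    if (denom == 0) {
      adeeg_diag("zero alpha+beta power: band ratio set to 0")
      return(0)
    }
    num / denom
  }
  c(total_power = total,
    psd_peak = if (any(inr)) max(pg$psd[inr]) else 0,
    psd_peak_to_peak = if (any(inr)) max(pg$psd[inr]) - min(pg$psd[inr]) else 0,
    delta_power = pw[["delta"]], theta_power = pw[["theta"]],
    alpha_power = pw[["alpha"]], beta_power = pw[["beta"]],
    gamma_power = pw[["gamma"]],
    r1 = ratio(pw[["delta"]]), r2 = ratio(pw[["theta"]]),
    r3 = ratio(pw[["delta"]] + pw[["theta"]]))
}

#' Frequency-domain features of one window
#'
#' Seven metrics treating the spectral power `w(f) = |X(f)|^2` on the
#' one-sided DFT grid restricted to 1-40 Hz as a weight distribution over
#' frequency: maximum frequency (largest `f` whose power exceeds `1e-6` of
#' the peak), sum of frequencies (total spectral weight, power units), mean
#' frequency, median frequency (smallest `f` where the cumulative weight
#' reaches half the total), peak frequency (smallest argmax on ties), and
#' the power-weighted spectral skewness and kurtosis. An all-zero spectrum
#' yields all zeros with a diagnostic.
#'
#' @param window Numeric sample vector (length >= 2).
#' @param fs Sampling rate in Hz.
#' @param freq_range Frequency range in Hz (default `c(1, 40)`).
#' @return Named numeric vector of length 7.
#' @export
frequency_features <- function(window, fs, freq_range = c(1, 40)) {
  if (length(window) < 2) stop("window must have at least 2 samples")
  n <- length(window)
  half <- floor(n / 2) + 1
  f <- (0:(half - 1)) * fs / n
  w <- (Mod(fft(window))[1:half])^2
  keep <- f >= freq_range[1] & f <= freq_range[2]
  f <- f[keep]; w <- w[keep]
  zero <- c(max_frequency = 0, sum_frequencies = 0, mean_frequency = 0,
            median_frequency = 0, peak_frequency = 0,
            spectral_skewness = 0, spectral_kurtosis = 0)
  if (!length(w) || max(w) == 0) {
    adeeg_diag("all-zero spectrum: frequency features set to 0")
    return(zero)
  }
  tot <- sum(w)
  mf <- sum(f * w) / tot
  cum <- cumsum(w)
  medf <- f[which(cum >= tot / 2)[1]]
  sdf <- sqrt(sum(w * (f - mf)^2) / tot)
  if (sdf == 0) {
    sk <- 0; ku <- 0
  } else {
    sk <- sum(w * (f - mf)^3) / tot / sdf^3
    ku <- sum(w * (f - mf)^4) / tot / sdf^4
  }
  c(max_frequency = max(f[w > 1e-6 * max(w)]),
    sum_frequencies = tot,
    mean_frequency = mf,
    median_frequency = medf,
    peak_frequency = f[which.max(w)],
    spectral_skewness = sk,
    spectral_kurtosis = ku)
}
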