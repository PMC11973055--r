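#' Preprocessing configuration
#'
#' @param target_fs Common sampling rate all recordings are brought to
#'   (Hz, default 256).
#' @param filter_order Butterworth order (default 5; applied forward and
#'   backward, so the effective attenuation order doubles).
#' @param band Pass band `c(low, high)` in Hz (default `c(1, 40)`).
#' @param resample_check_threshold Minimum acceptable spectral-fidelity
#'   correlation before [check_resampling_fidelity()] emits a diagnostic
#'   (default 0.99).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 256, filter_order = 5,
                              band = c(1, 40), resample_check_threshold = 0.99) {
  if (!(0 < band[1] && band[1] < band[2] && band[2] < target_fs / 2)) {
    stop("band must satisfy 0 < low < high < target_fs/2")
  }
  if (filter_order < 1) stop("filter_order must be >= 1")
  structure(list(target_fs = target_fs, filter_order = as.integer(filter_order),
                 band = band, resample_check_threshold = resample_check_threshold),
            class = "preprocess_config")
}

# Fourier-method resampling to an exact output length (anti-aliased by
# construction: the spectrum is truncated/zero-padded at the new Nyquist).
resample_fourier <- function(x, n_out) {
  n <- length(x)
  m <- n_out
  if (m == n) return(x)
  X <- fft(x)
  Y <- complex(m)
  kp <- min((n - 1) %/% 2, (m - 1) %/% 2)  # strictly positive bins kept
  Y[1] <- X[1]
  if (kp >= 1) {
    Y[2:(kp + 1)] <- X[2:(kp + 1)]
    Y[(m - kp + 1):m] <- X[(n - kp + 1):n]
  }
  if (m > n && n %% 2 == 0) {
    # upsampling past an even-length input: split its Nyquist bin
    Y[n %/% 2 + 1] <- X[n %/% 2 + 1] / 2
    Y[m - n %/% 2 + 1] <- X[n %/% 2 + 1] / 2
  } else if (m < n && m %% 2 == 0) {
    # downsampling to even length: fold the conjugate pair onto the new Nyquist
    Y[m %/% 2 + 1] <- X[m %/% 2 + 1] + X[n - m %/% 2 + 1]
  }
  Re(fft(Y, inverse = TRUE)) / n
}

#' Resample a recording to a target rate
#'
#' Fourier-method resampling of every channel; the output has exactly
#' `round(n * target_fs / fs)` samples per channel. A recording already at
#' the target rate is returned unchanged.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs Target sampling rate in Hz.
#' @return The resampled [eeg_recording()].
#' @export
resample_to_target <- function(rec, target_fs = 256) {
  validate_recording(rec)
  if (target_fs <= 0) stop("target_fs must be > 0")
  if (rec$fs == target_fs) return(rec)
  n_out <- round(ncol(rec$data) * target_fs / rec$fs)
  out <- t(apply(rec$data, 1, resample_fourier, n_out = n_out))
  eeg_recording(out, fs = target_fs, subject_id = rec$subject_id,
                group = rec$group, channel_names = rec$channel_names)
}

# one-sided magnitude spectrum (freq, |X|) of a vector
magnitude_spectrum <- function(x, fs) {
  n <- length(x)
  half <- floor(n / 2) + 1
  list(freq = (0:(half - 1)) * fs / n, mag = Mod(fft(x))[1:half])
}

#' Check spectral fidelity of resampling
#'
#' For each channel, the Pearson correlation between the magnitude spectra
#' of the original and resampled signals, interpolated onto a common 1-40 Hz
#' grid. The first and last 0.5 s of each signal are excluded to avoid
#' boundary transients. Values below the configured threshold trigger a
#' diagnostic; successful resampling of band-limited EEG gives correlations
#' near 1.
#'
#' @param original,resampled [eeg_recording()]s with the same channel count.
#' @param config A [preprocess_config()] (supplies the warning threshold).
#' @return Numeric vector of per-channel correlations in `[-1, 1]`.
#' @export
check_resampling_fidelity <- function(original, resampled,
                                      config = preprocess_config()) {
  validate_recording(original); validate_recording(resampled)
  if (nrow(original$data) != nrow(resampled$data)) {
    stop("channel counts differ between original and resampled recordings")
  }
  grid <- seq(1, 40, by = 0.25)
  trim <- function(x, fs) {
    k <- round(0.5 * fs)
    if (length(x) > 2 * k + 8) x[(k + 1):(length(x) - k)] else x
  }
  cors <- vapply(seq_len(nrow(original$data)), function(ch) {
    s1 <- magnitude_spectrum(trim(original$data[ch, ], original$fs), original$fs)
    s2 <- magnitude_spectrum(trim(resampled$data[ch, ], resampled$fs), resampled$fs)
    m1 <- approx(s1$freq, s1$mag, xout = grid, rule = 2)$y
    m2 <- approx(s2$freq, s2$mag, xout = grid, rule = 2)$y
    if (sd(m1) == 0 || sd(m2) == 0) return(0)
    cor(m1, m2)
  }, 0)
  low <- which(cors < config$resample_check_threshold)
  if (length(low)) {
    adeeg_diag("resampling fidelity below ", config$resample_check_threshold,
               " on channel(s) ", paste(original$channel_names[low], collapse = ", "),
               " (min ", format(min(cors), digits = 3), ")")
  }
  cors
}

#' RMS-normalize a recording channel-wise
#'
#' Divides each channel by its own root-mean-square over the full recording,
#' so every channel leaves with RMS exactly 1. Amplitude differences between
#' subjects and acquisition set-ups are thereby removed independent of the
#' recording duration.
#'
#' @param rec An [eeg_recording()].
#' @return The normalized [eeg_recording()].
#' @export
rms_normalize <- function(rec) {
  validate_recording(rec)
  rms <- sqrt(rowMeans(rec$data^2))
  if (any(rms == 0)) {
    stop("zero-RMS (flat) channel(s): ",
         paste(rec$channel_names[rms == 0], collapse = ", "))
  }
  rec$data <- rec$data / rms
  rec
}

#' Remove the per-channel mean
#'
#' Centers every channel at zero; the downstream time-frequency metrics
#' assume zero-centered data.
#'
#' @param rec An [eeg_recording()].
#' @return The centered [eeg_recording()].
#' @export
remove_mean <- function(rec) {
  validate_recording(rec)
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) application of a Butterworth band-pass of
#' the configured order and band to every channel. Zero-phase filtering is
#' used so that no phase distortion is introduced; the effective magnitude
#' response is the squared one-pass response.
#'
#' @param rec An [eeg_recording()] already at the target sampling rate.
#' @param config A [preprocess_config()].
#' @return The filtered [eeg_recording()].
#' @export
bandpass_filter <- function(rec, config = preprocess_config()) {
  validate_recording(rec)
  if (config$band[2] >= rec$fs / 2) {
    stop("band upper edge must be below Nyquist (fs/2 = ", rec$fs / 2, ")")
  }
  bf <- signal::butter(config$filter_order, config$band / (rec$fs / 2), type = "pass")
  rec$data <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rec
}

#' Preprocess a recording
#'
#' The full normalization chain, in order: resample to the target rate,
#' RMS-normalize each channel, remove the channel mean, band-pass filter.
#'
#' @param rec An [eeg_recording()].
#' @param config A [preprocess_config()].
#' @param check_fidelity If `TRUE` (default), compute the resampling
#'   fidelity correlations when resampling actually occurred and attach them
#'   as attribute `"resample_fidelity"`.
#' @return The preprocessed [eeg_recording()].
#' @export
preprocess_recording <- function(rec, config = preprocess_config(),
                                 check_fidelity = TRUE) {
  validate_recording(rec)
  resampled <- resample_to_target(rec, config$target_fs)
  fid <- NULL
  if (check_fidelity && rec$fs != config$target_fs) {
    fid <- check_resampling_fidelity(rec, resampled, config)
  }
  out <- bandpass_filter(remove_mean(rms_normalize(resampled)), config)
  if (!is.null(fid)) attr(out, "resample_fidelity") <- fid
  out
}
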