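#' Canonical EEG band edges (Hz)
#'
#' The five classical bands used throughout: delta 1-4, theta 4-8, alpha
#' 8-13, beta 13-30, gamma 30-40 Hz. Bands are half-open `[low, high)`
#' except gamma, whose upper edge (40 Hz) is included, so together they tile
#' the 1-40 Hz analysis range exactly.
#'
#' @format Named list of `c(low, high)` pairs.
#' @export
EEG_BANDS <- list(
  delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
  beta = c(13, 30), gamma = c(30, 40)
)

#' Define a synthetic group spectral profile
#'
#' A profile pins down the spectral "archetype" of one study group: relative
#' linear power per canonical band, the sampling rate the group is recorded
#' at, the slope of the 1/f background, and the ratio of structured band
#' power to background power.
#'
#' @param name Group label (`"control"`, `"mci"`, `"ad"`, or free-form).
#' @param band_weights Named numeric vector over
#'   `c("delta","theta","alpha","beta","gamma")`; relative expected power per
#'   band, all `>= 0`, at least one `> 0`.
#' @param sampling_rate Sampling rate in Hz; must exceed 80 Hz so the 40 Hz
#'   analysis edge stays below Nyquist.
#' @param pink_exponent Exponent of the `1/f^a` background (`>= 0`).
#' @param snr Ratio of total structured band power to background power;
#'   `Inf` disables the background.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name, band_weights, sampling_rate,
                          pink_exponent = 1, snr = 5) {
  bands <- names(EEG_BANDS)
  if (is.null(names(band_weights))) names(band_weights) <- bands
  band_weights <- band_weights[bands]
  if (any(is.na(band_weights)) || any(band_weights < 0) || !any(band_weights > 0)) {
    stop("band_weights must be >= 0 over all five bands with at least one > 0")
  }
  if (sampling_rate <= 2 * 40) stop("sampling_rate must exceed 80 Hz (Nyquist above 40 Hz)")
  if (pink_exponent < 0) stop("pink_exponent must be >= 0")
  if (snr <= 0) stop("snr must be > 0 (use Inf for no background)")
  structure(list(name = name, band_weights = band_weights,
                 sampling_rate = sampling_rate,
                 pink_exponent = pink_exponent, snr = snr),
            class = "group_profile")
}

#' Default group spectral profiles
#'
#' Encodes the classic EEG slowing effect of Alzheimer's disease: relative
#' to controls, the AD-like profile has elevated delta/theta power and
#' suppressed alpha/beta power (shifting the signal toward slow, more
#' regular activity, hence lower downstream complexity metrics); the
#' MCI-like profile is the elementwise midpoint. Controls are produced at
#' 200 Hz and patient groups at 256 Hz so the resampling path of the
#' preprocessing stage is always exercised.
#'
#' @return Named list of three [group_profile()] objects
#'   (`control`, `mci`, `ad`).
#' @export
default_profiles <- function() {
  w_control <- c(delta = 0.5, theta = 0.7, alpha = 1.5, beta = 1.0, gamma = 0.3)
  w_ad      <- c(delta = 1.5, theta = 1.4, alpha = 0.6, beta = 0.4, gamma = 0.2)
  list(
    control = group_profile("control", w_control, sampling_rate = 200),
    mci = group_profile("mci", (w_control + w_ad) / 2, sampling_rate = 256),
    ad = group_profile("ad", w_ad, sampling_rate = 256)
  )
}

#' Specify a synthetic cohort
#'
#' @param n_per_group Number of subjects per group.
#' @param duration Recording duration in seconds (>= 2).
#' @param n_channels Number of channels (default 19).
#' @param seed Integer seed driving all randomness, fanned out into
#'   per-subject per-channel substreams.
#' @param profiles List of [group_profile()] objects, one per group
#'   (default [default_profiles()]).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 7, duration = 60, n_channels = 19,
                        seed = 1, profiles = default_profiles()) {
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  if (duration < 2) stop("duration must be >= 2 s")
  if (n_channels < 1) stop("n_channels must be >= 1")
  for (p in profiles) stopifnot(inherits(p, "group_profile"))
  min_fs <- min(vapply(profiles, function(p) p$sampling_rate, 0))
  if (duration * min_fs < 2 * min_fs * 1.0) stop("duration too short for 1-s windows")
  structure(list(n_per_group = as.integer(n_per_group), duration = duration,
                 n_channels = as.integer(n_channels), seed = as.integer(seed),
                 profiles = profiles),
            class = "cohort_spec")
}

# Band-limited Gaussian noise: white noise put through the same 5th-order
# Butterworth band-pass family the preprocessing stage uses, then rescaled
# so the realized mean-square power equals `power` exactly.
band_noise <- function(n, fs, band, power) {
  bf <- signal::butter(5, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  r <- sqrt(mean(x^2))
  if (r == 0) return(numeric(n))
  x * sqrt(power) / r
}

# 1/f^a background via spectral shaping of white Gaussian noise,
# rescaled to the requested mean-square power.
pink_noise <- function(n, exponent, power) {
  if (power == 0) return(numeric(n))
  X <- fft(rnorm(n))
  k <- c(1, seq_len(n - 1))                 # DC handled separately
  f <- pmin(k, n - k + 1)                   # symmetric frequency index
  shape <- f^(-exponent / 2)
  shape[1] <- 0                             # remove DC
  x <- Re(fft(X * shape, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r == 0) return(numeric(n))
  x * sqrt(power) / r
}

#' Generate one synthetic EEG recording
#'
#' Each channel is an independent realization: the sum over the five
#' canonical bands of band-limited Gaussian noise, each band rescaled so its
#' power equals the profile's band weight, plus a `1/f^a` background whose
#' power is the total structured power divided by `snr`. Deterministic given
#' `(profile, duration, n_channels, seed)`.
#'
#' @param profile A [group_profile()].
#' @param duration Duration in seconds (>= 2).
#' @param n_channels Number of channels (default 19).
#' @param seed Integer seed.
#' @param subject_id Identifier stored on the recording.
#' @param subject_index Internal substream index; distinct values give
#'   independent subjects under one seed.
#' @return An [eeg_recording()] at the profile's sampling rate.
#' @export
generate_recording <- function(profile, duration, n_channels = 19, seed = 1,
                               subject_id = profile$name,
                               subject_index = 0L) {
  stopifnot(inherits(profile, "group_profile"))
  if (duration < 2) stop("duration must be >= 2 s")
  if (n_channels <= 0) stop("n_channels must be > 0")
  fs <- profile$sampling_rate
  n <- round(duration * fs)
  dat <- matrix(0, n_channels, n)
  w <- profile$band_weights
  total_structured <- sum(w)
  bg_power <- if (is.infinite(profile$snr)) 0 else total_structured / profile$snr
  for (ch in seq_len(n_channels)) {
    set.seed(derive_seed(seed, subject_index, ch))
    x <- numeric(n)
    for (b in names(EEG_BANDS)) {
      if (w[[b]] > 0) x <- x + band_noise(n, fs, EEG_BANDS[[b]], w[[b]])
    }
    x <- x + pink_noise(n, profile$pink_exponent, bg_power)
    dat[ch, ] <- x
  }
  eeg_recording(dat, fs = fs, subject_id = subject_id, group = profile$name,
                channel_names = if (n_channels == 19) CHANNELS_1020 else NULL)
}

#' Generate a synthetic cohort
#'
#' Produces `n_per_group` recordings per profile, each at its group's
#' sampling rate, with unique subject ids and reproducible data: subject
#' substreams are derived from the single cohort seed, so regenerating with
#' the same spec gives bit-identical recordings and adding subjects does not
#' perturb earlier ones.
#'
#' @param spec A [cohort_spec()].
#' @return List of [eeg_recording()] objects, grouped by profile order.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  recs <- list()
  gi <- 0L
  for (p in spec$profiles) {
    gi <- gi + 1L
    for (s in seq_len(spec$n_per_group)) {
      id <- sprintf("%s_%02d", p$name, s)
      recs[[id]] <- generate_recording(
        p, duration = spec$duration, n_channels = spec$n_channels,
        seed = spec$seed, subject_id = id,
        subject_index = gi * 1000L + s
      )
    }
  }
  recs
}

#' Write a cohort to a directory of per-subject CSV files
#'
#' @param recs List of recordings as returned by [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort_csv <- function(recs, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(recs, function(r) {
    p <- file.path(dir, paste0(r$subject_id, ".csv"))
    write_recording_csv(r, p)
    p
  }, "")
  invisible(paths)
}
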