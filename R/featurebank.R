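#' Canonical names of the 43-metric feature bank
#'
#' Fixed, documented feature order: 6 entropy metrics, 12 basic statistics,
#' 11 PSD metrics, 7 frequency-domain metrics and 7 fractal/complexity
#' metrics (6 + 12 + 11 + 7 + 7 = 43). The feature axis of every
#' [compute_feature_cube()] result follows this order.
#'
#' @return Character vector of length 43.
#' @export
feature_names <- function() {
  c(
    # entropy (6)
    "shannon_amplitude_entropy", "permutation_entropy", "spectral_entropy",
    "svd_entropy", "approximate_entropy", "sample_entropy",
    # basic statistics (12)
    "min", "max", "mean", "rms", "variance", "std", "crest_factor",
    "skewness", "kurtosis", "p25", "p50", "p75",
    # power spectral density (11)
    "total_power", "psd_peak", "psd_peak_to_peak", "delta_power",
    "theta_power", "alpha_power", "beta_power", "gamma_power",
    "r1", "r2", "r3",
    # frequency domain (7)
    "max_frequency", "sum_frequencies", "mean_frequency", "median_frequency",
    "peak_frequency", "spectral_skewness", "spectral_kurtosis",
    # fractal dimension and complexity (7)
    "zero_crossings", "katz_fd", "higuchi_fd", "dfa_alpha", "petrosian_fd",
    "hjorth_mobility", "hjorth_complexity"
  )
}

# all 43 features of one window, in canonical order
window_features <- function(window, fs, params) {
  c(entropy_features(window, fs, params),
    basic_stat_features(window),
    psd_features(window, fs, params),
    frequency_features(window, fs, params$freq_range),
    fractal_complexity_features(window, fs, params))
}

#' Compute the per-subject feature cube
#'
#' Slides a window over every channel of a (preprocessed) recording and
#' computes the 43-metric bank on each window, yielding a
#' channel x window x feature array.
#'
#' @param rec A preprocessed [eeg_recording()].
#' @param wcfg A [windowing_config()].
#' @param params A [feature_params()].
#' @return An object of class `feature_cube`: list with `subject_id`,
#'   `group`, `channel_names`, `feature_names`, `window_times` and `values`
#'   (channel x window x feature array).
#' @export
compute_feature_cube <- function(rec, wcfg = windowing_config(),
                                 params = feature_params()) {
  validate_recording(rec)
  fn <- feature_names()
  ws <- window_signal(rec$data[1, ], rec$fs, wcfg)
  nwin <- length(ws$windows)
  nch <- nrow(rec$data)
  vals <- array(NA_real_, dim = c(nch, nwin, length(fn)),
                dimnames = list(rec$channel_names, NULL, fn))
  for (ch in seq_len(nch)) {
    w <- if (ch == 1) ws else window_signal(rec$data[ch, ], rec$fs, wcfg)
    for (i in seq_len(nwin)) {
      vals[ch, i, ] <- window_features(w$windows[[i]], rec$fs, params)
    }
  }
  if (any(!is.finite(vals))) {
    bad <- which(!is.finite(vals), arr.ind = TRUE)
    stop("non-finite feature values, first at channel ", bad[1, 1],
         " window ", bad[1, 2], " feature ", fn[bad[1, 3]])
  }
  structure(list(subject_id = rec$subject_id, group = rec$group,
                 channel_names = rec$channel_names, feature_names = fn,
                 window_times = ws$times, values = vals),
            class = "feature_cube")
}

#' @export
print.feature_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_cube> %s (group: %s): %d channels x %d windows x %d features\n",
              x$subject_id, x$group, d[1], d[2], d[3]))
  invisible(x)
}

#' Write a feature cube as a long-format CSV
#'
#' One row per (channel, window, feature) triple with columns
#' `channel, window_index, feature_name, value`; metadata carried in
#' comment header lines.
#'
#' @param cube A [compute_feature_cube()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feature_cube_csv <- function(cube, path) {
  d <- dim(cube$values)
  long <- data.frame(
    channel = rep(cube$channel_names, times = d[2] * d[3]),
    window_index = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    feature_name = rep(cube$feature_names, each = d[1] * d[2]),
    value = as.vector(cube$values)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# subject_id=%s", cube$subject_id),
               sprintf("# group=%s", cube$group)), con)
  utils::write.table(long, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format feature cube CSV
#'
#' @param path File written by [write_feature_cube_csv()].
#' @return A `feature_cube`.
#' @export
read_feature_cube_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(subject_id = basename(path), group = NA_character_)
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub("=.*$", "", kv)
    if (key %in% names(meta)) meta[[key]] <- sub("^[^=]*=", "", kv)
  }
  df <- utils::read.csv(textConnection(lines[!grepl("^#", lines)]))
  chn <- unique(df$channel)
  fn <- feature_names()
  nwin <- max(df$window_index)
  vals <- array(NA_real_, dim = c(length(chn), nwin, length(fn)),
                dimnames = list(chn, NULL, fn))
  vals[cbind(match(df$channel, chn), df$window_index,
             match(df$feature_name, fn))] <- df$value
  structure(list(subject_id = meta$subject_id, group = meta$group,
                 channel_names = chn, feature_names = fn,
                 window_times = seq_len(nwin) - 1, values = vals),
            class = "feature_cube")
}
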