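#' Feature extraction parameters
#'
#' Tunables of the 43-metric feature bank. The defaults are the
#' literature-standard choices for 1-s EEG windows.
#'
#' @param entropy_embedding_m Embedding dimension for approximate and sample
#'   entropy (default 2).
#' @param entropy_tolerance_r Tolerance as a fraction of the window's
#'   (population) standard deviation (default 0.2).
#' @param perm_order Ordinal pattern length for permutation entropy
#'   (default 3).
#' @param perm_delay Embedding delay for permutation entropy (default 1).
#' @param svd_order,svd_delay Delay-embedding order and delay for SVD
#'   entropy (defaults 3 and 1).
#' @param hist_bins Number of equal-width amplitude bins for the histogram
#'   (Shannon) entropy (default 16).
#' @param higuchi_kmax Maximum curve-length scale for the Higuchi fractal
#'   dimension (default 10).
#' @param dfa_scales Integer window sizes for detrended fluctuation
#'   analysis; `NULL` (default) uses 10 log-spaced scales between 4 and
#'   N/4 samples, derived per window. Scales exceeding N/4 are dropped.
#' @param band_edges Band definition used by the spectral features
#'   (default [EEG_BANDS]).
#' @param freq_range Frequency range (Hz) over which spectral features are
#'   evaluated (default `c(1, 40)`).
#' @return An object of class `feature_params`.
#' @export
feature_params <- function(entropy_embedding_m = 2L, entropy_tolerance_r = 0.2,
                           perm_order = 3L, perm_delay = 1L,
                           svd_order = 3L, svd_delay = 1L,
                           hist_bins = 16L, higuchi_kmax = 10L,
                           dfa_scales = NULL, band_edges = EEG_BANDS,
                           freq_range = c(1, 40)) {
  if (entropy_embedding_m < 1) stop("entropy_embedding_m must be >= 1")
  if (entropy_tolerance_r <= 0) stop("entropy_tolerance_r must be > 0")
  if (perm_order < 2) stop("perm_order must be >= 2")
  if (higuchi_kmax < 2) stop("higuchi_kmax must be >= 2")
  edges <- unlist(band_edges)
  if (any(diff(unique(edges)) <= 0)) stop("band edges must be strictly increasing")
  structure(list(entropy_embedding_m = as.integer(entropy_embedding_m),
                 entropy_tolerance_r = entropy_tolerance_r,
                 perm_order = as.integer(perm_order),
                 perm_delay = as.integer(perm_delay),
                 svd_order = as.integer(svd_order),
                 svd_delay = as.integer(svd_delay),
                 hist_bins = as.integer(hist_bins),
                 higuchi_kmax = as.integer(higuchi_kmax),
                 dfa_scales = dfa_scales,
                 band_edges = band_edges,
                 freq_range = freq_range),
            class = "feature_params")
}

# population (divisor-N) moments
pop_var <- function(x) mean((x - mean(x))^2)
pop_sd <- function(x) sqrt(pop_var(x))

# One-sided periodogram: PSD(f) = |X(f)|^2 / (fs * N), interior bins doubled
# so that sum(PSD) * df equals the signal's mean-square power.
periodogram_psd <- function(x, fs) {
  n <- length(x)
  half <- floor(n / 2) + 1
  p <- (Mod(fft(x))[1:half])^2 / (fs * n)
  if (n %% 2 == 0) {
    if (half > 2) p[2:(half - 1)] <- 2 * p[2:(half - 1)]
  } else {
    if (half > 1) p[2:half] <- 2 * p[2:half]
  }
  list(freq = (0:(half - 1)) * fs / n, psd = p, df = fs / n)
}
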