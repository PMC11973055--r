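#' Entropy features of one window
#'
#' Six regularity/complexity metrics: Shannon entropy of the amplitude
#' histogram, permutation entropy, spectral entropy, SVD entropy,
#' approximate entropy and sample entropy. Reduced values of all six are the
#' classic signature of the more regular, less complex EEG of Alzheimer's
#' disease.
#'
#' Conventions: permutation, spectral and SVD entropies are normalized to
#' `[0, 1]` (by `log(order!)`, the log bin count and `log(order)`
#' respectively); the amplitude-histogram entropy uses natural log,
#' unnormalized. ApEn and SampEn use Chebyshev distance with tolerance
#' `r` times the window standard deviation; SampEn is the standard
#' `-ln(A/B)` with self-matches
#' excluded. A constant (zero-variance) window yields 0 for all six, with a
#' diagnostic.
#'
#' @param window Numeric sample vector (length >= `perm_order + 1` and
#'   `entropy_embedding_m + 2`).
#' @param fs Sampling rate in Hz.
#' @param params A [feature_params()].
#' @return Named numeric vector of length 6.
#' @export
entropy_features <- function(window, fs, params = feature_params()) {
  n <- length(window)
  if (n < max(params$perm_order + 1, params$entropy_embedding_m + 2)) {
    stop("window too short for the configured entropy embeddings")
  }
  out <- c(shannon_amplitude_entropy = 0, permutation_entropy = 0,
           spectral_entropy = 0, svd_entropy = 0,
           approximate_entropy = 0, sample_entropy = 0)
  if (pop_sd(window) == 0) {
    adeeg_diag("constant window: entropy features set to 0")
    return(out)
  }
  out["shannon_amplitude_entropy"] <- hist_entropy(window, params$hist_bins)
  out["permutation_entropy"] <- perm_entropy(window, params$perm_order,
                                             params$perm_delay)
  out["spectral_entropy"] <- spectral_entropy(window, fs)
  out["svd_entropy"] <- svd_entropy(window, params$svd_order, params$svd_delay)
  r <- params$entropy_tolerance_r * pop_sd(window)
  ae <- apen_sampen(window, params$entropy_embedding_m, r)
  out["approximate_entropy"] <- ae$apen
  out["sample_entropy"] <- ae$sampen
  out
}

hist_entropy <- function(x, bins) {
  if (diff(range(x)) == 0) return(0)
  idx <- findInterval(x, seq(min(x), max(x), length.out = bins + 1),
                      rightmost.closed = TRUE, all.inside = TRUE)
  p <- tabulate(idx, nbins = bins) / length(x)
  p <- p[p > 0]
  -sum(p * log(p))
}

# ordinal pattern index via Lehmer code; ties broken by position
# (equal values keep their temporal order)
ordinal_patterns <- function(x, order, delay) {
  n <- length(x)
  k <- n - (order - 1) * delay
  if (k < 1) stop("window too short for permutation embedding")
  emb <- vapply(seq_len(order), function(j) x[(1 + (j - 1) * delay):((j - 1) * delay + k)],
                numeric(k))
  if (k == 1) emb <- matrix(emb, nrow = 1)
  code <- integer(k)
  for (i in seq_len(order)) {
    less <- rep(0L, k)
    for (j in seq_len(order)) {
      if (j == i) next
      if (j < i) less <- less + (emb[, j] <= emb[, i])
      else less <- less + (emb[, j] < emb[, i])
    }
    code <- code * order + less
  }
  code
}

perm_entropy <- function(x, order, delay) {
  code <- ordinal_patterns(x, order, delay)
  p <- tabulate(code + 1L, nbins = order^order) / length(code)
  p <- p[p > 0]
  -sum(p * log(p)) / log(factorial(order))
}

spectral_entropy <- function(x, fs) {
  pg <- periodogram_psd(x, fs)
  p <- pg$psd
  tot <- sum(p)
  if (tot == 0) return(0)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(length(pg$psd))
}

svd_entropy <- function(x, order, delay) {
  k <- length(x) - (order - 1) * delay
  emb <- vapply(seq_len(order), function(j) x[(1 + (j - 1) * delay):((j - 1) * delay + k)],
                numeric(k))
  s <- svd(emb, nu = 0, nv = 0)$d
  s <- s / sum(s)
  s <- s[s > 0]
  -sum(s * log(s)) / log(order)
}

# Approximate and sample entropy from the compiled template-match counter
# (Chebyshev distance). ApEn: phi_m - phi_{m+1} with self-matches included
# (Pincus). SampEn: -ln(A/B) over the common N-m template set, self-matches
# excluded.
apen_sampen <- function(x, m, r) {
  cnt <- .apen_sampen_counts(x, as.integer(m), r)
  apen <- cnt[1] - cnt[2]
  A <- cnt[3]; B <- cnt[4]
  sampen <- if (A > 0 && B > 0) -log(A / B) else {
    adeeg_diag("no template matches: sample entropy set to 0")
    0
  }
  list(apen = apen, sampen = sampen)
}
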