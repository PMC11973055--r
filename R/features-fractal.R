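#' Fractal dimension and complexity features of one window
#'
#' Seven waveform-complexity descriptors: number of zero-crossings (strict
#' sign changes, zeros skipped), Katz fractal dimension, Higuchi fractal
#' dimension, DFA scaling exponent, Petrosian fractal dimension, and the
#' Hjorth mobility and complexity. First differences are taken in discrete
#' sample units (not scaled by `fs`), so values are comparable across runs
#' at a common sampling rate. A zero-variance window yields 0 for the
#' Higuchi dimension and the Hjorth parameters, with a diagnostic.
#'
#' @param window Numeric sample vector (length >= `3 * higuchi_kmax`).
#' @param fs Sampling rate in Hz (kept for interface symmetry; the discrete
#'   conventions make these metrics rate-free).
#' @param params A [feature_params()].
#' @return Named numeric vector of length 7.
#' @export
fractal_complexity_features <- function(window, fs, params = feature_params()) {
  n <- length(window)
  if (n < 2) stop("window must have at least 2 samples")
  if (n < 3 * params$higuchi_kmax) {
    stop("window must have at least 3 * higuchi_kmax samples")
  }
  v0 <- pop_var(window)
  degenerate <- v0 == 0
  if (degenerate) adeeg_diag("constant window: Higuchi/Hjorth features set to 0")
  c(zero_crossings = zero_crossings(window),
    katz_fd = katz_fd(window),
    higuchi_fd = if (degenerate) 0 else higuchi_fd(window, params$higuchi_kmax),
    dfa_alpha = if (degenerate) 0 else dfa_alpha(window, params$dfa_scales),
    petrosian_fd = petrosian_fd(window),
    hjorth_mobility = if (degenerate) 0 else hjorth(window)[1],
    hjorth_complexity = if (degenerate) 0 else hjorth(window)[2])
}

zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(diff(s) != 0)
}

# Katz: log10(n) / (log10(n) + log10(d / L)), n = number of steps,
# L = total path length, d = maximal distance from the first sample.
katz_fd <- function(x) {
  n <- length(x) - 1
  L <- sum(abs(diff(x)))
  if (L == 0) return(0)
  d <- max(abs(x - x[1]))
  if (d == 0) return(0)
  log10(n) / (log10(n) + log10(d / L))
}

# Higuchi: average normalized curve length L(k) over offsets, slope of
# log L(k) vs log(1/k) for k = 1..kmax (lengths from the compiled kernel).
higuchi_fd <- function(x, kmax) {
  lk <- .higuchi_lengths(x, as.integer(kmax))
  ok <- lk > 0
  if (sum(ok) < 2) return(0)
  ls_slope(log(1 / seq_len(kmax)[ok]), log(lk[ok]))
}

# least-squares slope of y on x
ls_slope <- function(x, y) {
  mx <- mean(x)
  sum((x - mx) * (y - mean(y))) / sum((x - mx)^2)
}

# DFA: cumulative-sum profile, non-overlapping windows, linear detrending;
# scaling exponent = slope of log F(n) vs log n.
dfa_alpha <- function(x, scales = NULL) {
  n <- length(x)
  if (is.null(scales)) {
    scales <- unique(round(exp(seq(log(4), log(max(4, n %/% 4)), length.out = 10))))
  }
  scales <- scales[scales >= 4 & scales <= n %/% 4]
  if (length(scales) < 2) return(0)
  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(s) {
    k <- n %/% s
    seg <- matrix(y[seq_len(k * s)], nrow = s)
    t_ <- seq_len(s)
    # residuals of per-segment linear fits via one projection
    H <- cbind(1, t_)
    res <- seg - H %*% solve(crossprod(H), crossprod(H, seg))
    sqrt(mean(res^2))
  }, 0)
  ok <- fl > 0
  if (sum(ok) < 2) return(0)
  ls_slope(log(scales[ok]), log(fl[ok]))
}

# Petrosian: log10(N) / (log10(N) + log10(N / (N + 0.4 Nd))),
# Nd = sign changes of the first difference.
petrosian_fd <- function(x) {
  n <- length(x)
  s <- sign(diff(x))
  s <- s[s != 0]
  nd <- if (length(s) < 2) 0 else sum(diff(s) != 0)
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

hjorth <- function(x) {
  v0 <- pop_var(x)
  d1 <- diff(x)
  v1 <- pop_var(d1)
  if (v0 == 0 || v1 == 0) return(c(0, 0))
  v2 <- pop_var(diff(d1))
  mob <- sqrt(v1 / v0)
  c(mob, sqrt(v2 / v1) / mob)
}
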