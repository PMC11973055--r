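# Independent brute-force reference implementations used as oracles.
# Deliberately written as naive loops, sharing no code with the package.

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  cheb <- function(a, b) max(abs(a - b))
  count <- function(len) {
    k <- n - m  # common template count
    hits <- 0
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        if (cheb(x[i:(i + len - 1)], x[j:(j + len - 1)]) <= r) hits <- hits + 1
      }
    }
    hits
  }
  B <- count(m)
  A <- count(m + 1)
  if (A == 0 || B == 0) return(0)
  -log(A / B)
}

oracle_apen <- function(x, m, r) {
  n <- length(x)
  phi <- function(mm) {
    k <- n - mm + 1
    tot <- 0
    for (i in 1:k) {
      c_i <- 0
      for (j in 1:k) {
        if (max(abs(x[i:(i + mm - 1)] - x[j:(j + mm - 1)])) <= r) c_i <- c_i + 1
      }
      tot <- tot + log(c_i / k)
    }
    tot / k
  }
  phi(m) - phi(m + 1)
}

oracle_perm_entropy <- function(x, order, delay) {
  n <- length(x)
  k <- n - (order - 1) * delay
  pats <- character(k)
  for (i in 1:k) {
    v <- x[seq(i, by = delay, length.out = order)]
    pats[i] <- paste(order(v), collapse = "-")  # stable: ties keep position
  }
  p <- table(pats) / k
  -sum(p * log(p)) / log(factorial(order))
}

oracle_petrosian <- function(x) {
  n <- length(x)
  dx <- diff(x)
  s <- sign(dx)
  s <- s[s != 0]
  nd <- 0
  if (length(s) >= 2) {
    for (i in 2:length(s)) if (s[i] != s[i - 1]) nd <- nd + 1
  }
  log10(n) / (log10(n) + log10(n / (n + 0.4 * nd)))
}

oracle_higuchi <- function(x, kmax) {
  n <- length(x)
  lk <- numeric(kmax)
  for (k in 1:kmax) {
    lm <- numeric(k)
    for (m in 1:k) {
      nseg <- floor((n - m) / k)
      s <- 0
      for (i in 1:nseg) s <- s + abs(x[m + i * k] - x[m + (i - 1) * k])
      lm[m] <- s * (n - 1) / (nseg * k^2)
    }
    lk[k] <- mean(lm)
  }
  fit <- lm(log(lk) ~ log(1 / (1:kmax)))
  unname(coef(fit)[2])
}

# type-7 linear-interpolation quantile, written out longhand
oracle_quantile7 <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# periodogram band power by direct DFT summation
oracle_band_power <- function(x, fs, lo, hi, include_upper = FALSE) {
  n <- length(x)
  half <- floor(n / 2) + 1
  X <- fft(x)[1:half]
  psd <- Mod(X)^2 / (fs * n)
  if (n %% 2 == 0) { if (half > 2) psd[2:(half - 1)] <- 2 * psd[2:(half - 1)] } else {
    psd[2:half] <- 2 * psd[2:half]
  }
  f <- (0:(half - 1)) * fs / n
  sel <- if (include_upper) f >= lo & f <= hi else f >= lo & f < hi
  sum(psd[sel]) * fs / n
}
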