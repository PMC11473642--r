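# Shared signal-processing primitives (FFT based). Kept internal.

next_pow2 <- function(n) 2^ceiling(log2(max(1, n)))

# Analytic signal via frequency-domain Hilbert transform.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Linear convolution of x with FIR kernel h via FFT, keeping the "same"
# central part so that a symmetric (linear-phase) kernel is applied with
# zero net delay. Equivalent to filtering plus group-delay compensation.
fft_conv_same <- function(x, h) {
  nx <- length(x); nh <- length(h)
  nfft <- next_pow2(nx + nh - 1)
  y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - nx))) *
                     stats::fft(c(h, numeric(nfft - nh))), inverse = TRUE)) / nfft
  delay <- (nh - 1) %/% 2
  y[(delay + 1):(delay + nx)]
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

# Short-time Fourier transform: complex matrix (freq bins x frames).
stft_mat <- function(x, frame, hop, window = hann_window(frame)) {
  n <- length(x)
  starts <- seq(1, max(1, n - frame + 1), by = hop)
  S <- matrix(0 + 0i, nrow = frame, ncol = length(starts))
  for (i in seq_along(starts)) {
    seg <- x[starts[i]:(starts[i] + frame - 1)]
    S[, i] <- stats::fft(seg * window)
  }
  attr(S, "starts") <- starts
  attr(S, "n") <- n
  attr(S, "window") <- window
  S
}

# Weighted overlap-add inverse of stft_mat (same window for synthesis).
istft_mat <- function(S) {
  starts <- attr(S, "starts"); n <- attr(S, "n"); w <- attr(S, "window")
  frame <- nrow(S)
  y <- numeric(n); norm <- numeric(n)
  for (i in seq_along(starts)) {
    seg <- Re(stats::fft(S[, i], inverse = TRUE)) / frame
    idx <- starts[i]:(starts[i] + frame - 1)
    y[idx] <- y[idx] + seg * w
    norm[idx] <- norm[idx] + w^2
  }
  # samples with negligible window coverage (frame edges at the signal
  # boundary) cannot be reconstructed reliably once spectra are modified
  low <- norm < 0.05 * stats::median(norm)
  y[low] <- 0
  norm[low] <- 1
  y / norm
}

# 1/f^alpha ("pink" for alpha = 1) noise by spectral shaping of white noise.
colored_noise <- function(n, alpha = 1, fs = 1) {
  nfft <- next_pow2(n)
  f <- c(1, seq_len(nfft / 2), rev(seq_len(nfft / 2 - 1)))  # avoid DC blowup
  shape <- 1 / f^(alpha / 2)
  X <- stats::fft(stats::rnorm(nfft)) * shape
  x <- Re(stats::fft(X, inverse = TRUE)) / nfft
  x <- x[seq_len(n)]
  x / stats::sd(x)
}

# Pearson correlation that tolerates zero-variance inputs (returns NA).
safe_cor <- function(x, y) {
  if (stats::sd(x) < 1e-300 || stats::sd(y) < 1e-300) return(NA_real_)
  stats::cor(x, y)
}

ms_to_samples <- function(ms, fs) as.integer(round(ms / 1000 * fs))

rms <- function(x) sqrt(mean(x^2))
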