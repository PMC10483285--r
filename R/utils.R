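# Internal numerical helpers.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Analytic signal via the frequency-domain Hilbert transform; returns a
# complex vector whose argument is the instantaneous phase.
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# 1/f (power slope -1) background noise with the requested RMS.
pink_noise <- function(n, rms) {
  white <- rnorm(n)
  X <- fft(white)
  f <- c(1, seq_len(n - 1))            # guard DC
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  X <- X / sqrt(f)
  x <- Re(fft(X, inverse = TRUE) / n)
  x * rms / stats::sd(x)
}

# Band-limited 1/f background for EEG synthesis: the pink process is built
# at fs/decimate (linear upsampling happens in C++ when it is added to the
# signal), which keeps the exact 1/f shape over the whole 0.5-30 Hz
# analysis band while costing a fraction of the draws. Columns are
# independent channels.
pink_noise_low <- function(n, nch, rms, decimate = 8L) {
  m <- stats::nextn(ceiling(n / decimate) + 1L, c(2, 3, 5))  # FFT-friendly
  W <- matrix(rnorm(m * nch), m, nch)
  X <- stats::mvfft(W)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)
  X <- X / sqrt(f)
  low <- Re(stats::mvfft(X, inverse = TRUE) / m)
  sweep(low, 2, apply(low, 2, stats::sd) / rms, "/")
}

# Steady-state initial conditions for one IIR pass (the standard
# companion-matrix construction), so filtfilt transients are minimal.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  comp <- matrix(0, n - 1, n - 1)
  comp[1, ] <- -a[-1]
  if (n > 2) comp[cbind(2:(n - 1), 1:(n - 2))] <- 1
  solve(diag(n - 1) - t(comp), b[-1] - a[-1] * b[1])
}

# Zero-phase forward-backward IIR pass with odd-reflection padding.
fast_filtfilt <- function(b, a, x) {
  cpp_filtfilt(b, a, x, lfilter_zi(b, a))
}

# Smooth stationary Gaussian noise with Gaussian autocorrelation
# exp(-t^2 / (2 T^2)), synthesized spectrally (so its power is essentially
# band-limited to |f| < ~1/(2T), which a band-pass filter transmits without
# clipping) and normalized to an exact per-column sd. Used as phase jitter.
smooth_noise_matrix <- function(nk, ncols, dt, sd_target, T) {
  if (sd_target == 0) return(matrix(0, nk, ncols))
  m <- stats::nextn(nk + ceiling(8 * T / dt), c(2, 3, 5))
  W <- matrix(rnorm(m * ncols), m, ncols)
  k <- c(0:(m %/% 2), -rev(seq_len(m - m %/% 2 - 1)))
  f <- k / (m * dt)
  H <- exp(-pi^2 * T^2 * f^2)            # sqrt of the Gaussian-shaped PSD
  out <- Re(stats::mvfft(stats::mvfft(W) * H, inverse = TRUE) / m)
  out <- out[seq_len(nk), , drop = FALSE]
  sweep(out, 2, apply(out, 2, stats::sd) / sd_target, "/")
}

# Draw per-subject reproducible sub-seeds below 2^31.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
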