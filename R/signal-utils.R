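# Low-level spectral primitives shared across modules.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal of a real vector; its modulus is the
#' instantaneous amplitude envelope used by the spindle-burst detector.
#'
#' @param x Numeric vector.
#' @return Complex vector of the same length.
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' env <- Mod(analytic_signal(sin(2 * pi * 10 * t)))
analytic_signal <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort("`x` must be a finite numeric vector.", class = "lamindev_numeric_error")
  }
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Welch power spectral density
#'
#' Segment-averaged Hamming-windowed periodograms over non-overlapping
#' segments (default 4 s, the convention used throughout the package for both
#' baseline spectra and the 50 Hz channel QC).
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param seg_sec Segment length in seconds; segments do not overlap.
#' @return A tibble with columns `freq` (Hz) and `power` (signal units^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_sec = 4) {
  nseg <- floor(seg_sec * fs)
  if (length(x) < nseg) {
    abort(
      sprintf("signal (%d samples) shorter than one %g s Welch segment", length(x), seg_sec),
      class = "lamindev_length_error"
    )
  }
  k <- floor(length(x) / nseg)
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(nseg) / (nseg + 1))
  u <- sum(w^2)
  nf <- floor(nseg / 2) + 1
  acc <- numeric(nf)
  for (i in seq_len(k)) {
    seg <- x[((i - 1) * nseg + 1):(i * nseg)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(fft(seg))^2 / (fs * u)
    p <- p[seq_len(nf)]
    # fold negative frequencies into the one-sided estimate
    if (nseg %% 2 == 0) p[2:(nf - 1)] <- 2 * p[2:(nf - 1)] else p[2:nf] <- 2 * p[2:nf]
    acc <- acc + p
  }
  tibble(freq = (seq_len(nf) - 1) * fs / nseg, power = acc / k)
}

#' Continuous wavelet transform with a complex Morlet mother wavelet
#'
#' FFT-based CWT magnitude on a log-spaced frequency axis. The Morlet
#' centre parameter `omega0 = 6` gives the usual time-frequency trade-off for
#' 5-50 Hz band events.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate, Hz.
#' @param freqs Analysis frequencies, Hz (default 48 log-spaced over 5-50 Hz).
#' @param omega0 Morlet centre frequency parameter (unitless).
#' @return List with `freqs`, `time` (s) and `magnitude` (freq x time matrix).
#' @export
morlet_cwt <- function(x, fs, freqs = exp(seq(log(5), log(50), length.out = 48)),
                       omega0 = 6) {
  n <- length(x)
  X <- fft(x)
  omega <- 2 * pi * fs * c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) / n
  mag <- matrix(0, nrow = length(freqs), ncol = n)
  for (i in seq_along(freqs)) {
    s <- omega0 / (2 * pi * freqs[i])
    psi <- pi^(-0.25) * exp(-0.5 * (s * omega - omega0)^2) * (omega > 0)
    mag[i, ] <- Mod(fft(X * sqrt(s) * psi, inverse = TRUE) / n)
  }
  list(freqs = freqs, time = (seq_len(n) - 1) / fs, magnitude = mag)
}

#' Pink (1/f) noise
#'
#' Spectrally shaped Gaussian noise with power spectral density proportional
#' to 1/f^exponent, scaled to a target standard deviation. Used as the
#' background process of the synthetic-recording generator.
#'
#' @param n Number of samples.
#' @param exponent PSD exponent (1 = pink).
#' @param sd Target standard deviation of the output.
#' @return Numeric vector of length `n`.
#' @export
pink_noise <- function(n, exponent = 1, sd = 1) {
  white <- fft(rnorm(n))
  k <- seq(0, n - 1)
  f <- pmin(k, n - k) # symmetric frequency index keeps the spectrum Hermitian
  f[1] <- 1 # guard DC
  shaped <- white * f^(-exponent / 2)
  x <- Re(fft(shaped, inverse = TRUE) / n)
  x <- x - mean(x)
  x * sd / stats::sd(x)
}

# zero-padded centred boxcar; conserves the sum of x
boxcar_smooth <- function(x, k) {
  if (k %% 2 != 1) abort("boxcar width must be odd", class = "lamindev_config_error")
  half <- (k - 1) / 2
  xp <- c(numeric(half), x, numeric(half))
  out <- numeric(length(x))
  for (i in seq_along(x)) out[i] <- mean(xp[i:(i + k - 1)])
  out
}
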