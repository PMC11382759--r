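#' @importFrom stats fft mvfft approx rnorm runif quantile median sd var
#' @importFrom signal butter filter fir1 fftfilt freqz
NULL

#' Analytic signal via the discrete Hilbert transform
#'
#' Returns the complex analytic signal whose real part is `x` and whose
#' imaginary part is the Hilbert transform of `x`, computed by one-sided
#' doubling of the discrete spectrum.
#'
#' @param x numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  if (n < 2L) return(as.complex(x))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Odd (point-symmetric) reflection padding, as used by zero-phase filtering
# routines to suppress edge transients.
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  if (pad < 1L) return(list(x = x, pad = 0L))
  head_ext <- 2 * x[1L] - x[(pad + 1L):2L]
  tail_ext <- 2 * x[n] - x[(n - 1L):(n - pad)]
  list(x = c(head_ext, x, tail_ext), pad = pad)
}

#' Zero-phase IIR filtering (forward-backward)
#'
#' Applies the filter once forward and once backward so that the net phase
#' response is zero and the magnitude response is squared.  The signal is
#' extended by odd reflection before filtering to suppress edge transients.
#'
#' @param filt an `Arma` filter from [signal::butter()] (or a list with
#'   elements `b`, `a`).
#' @param x numeric vector.
#' @return filtered vector, same length as `x`.
#' @keywords internal
filtfilt_reflect <- function(filt, x) {
  b <- filt$b
  a <- filt$a
  n <- length(x)
  ext <- reflect_pad(x, 3L * (max(length(a), length(b)) - 1L) * 4L)
  y <- signal::filter(b, a, ext$x)
  y <- rev(signal::filter(b, a, rev(y)))
  y[(ext$pad + 1L):(ext$pad + n)]
}

# Design a zero-phase Butterworth band-pass.  `order` is the prototype
# (pre-reflection) order, as filter orders are conventionally quoted for
# forward-backward application.
butter_bandpass <- function(low_hz, high_hz, fs, order) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
}

butter_lowpass <- function(cutoff_hz, fs, order) {
  nyq <- fs / 2
  if (!(cutoff_hz > 0 && cutoff_hz < nyq))
    stop("cutoff must lie in (0, Nyquist)")
  signal::butter(order, cutoff_hz / nyq, type = "low")
}

#' Fourier-domain resampling
#'
#' Resamples a uniformly sampled signal to a new number of samples by
#' truncating or zero-padding its discrete spectrum.  Exact for band-limited
#' signals and intrinsically anti-aliased: frequency content above the new
#' Nyquist is removed.
#'
#' @param x numeric vector.
#' @param n_out target number of samples.
#' @return numeric vector of length `n_out`.
#' @keywords internal
fft_resample <- function(x, n_out) {
  n_in <- length(x)
  n_out <- as.integer(round(n_out))
  if (n_out == n_in) return(x)
  X <- fft(x)
  Y <- complex(n_out)
  n_keep <- min(n_in, n_out)
  half <- (n_keep + 1L) %/% 2L          # positive-frequency bins (excl. DC)
  Y[1L] <- X[1L]
  if (half > 1L) {
    Y[2L:half] <- X[2L:half]
    Y[(n_out - half + 2L):n_out] <- X[(n_in - half + 2L):n_in]
  }
  if (n_keep %% 2L == 0L) {
    # split the shared Nyquist bin to keep the result real-valued
    ny <- X[n_keep / 2L + 1L]
    if (n_out > n_in) {
      Y[n_keep / 2L + 1L] <- ny / 2
      Y[n_out - n_keep / 2L + 1L] <- Conj(ny) / 2
    } else {
      Y[n_keep / 2L + 1L] <- Re(ny)
    }
  }
  Re(fft(Y, inverse = TRUE)) / n_in
}

# Zero-phase application of a linear-phase FIR filter (odd length = 2k+1
# taps): reflect-pad, overlap-free FFT convolution, compensate group delay.
fir_filter_zero_phase <- function(b, x) {
  n <- length(x)
  delay <- (length(b) - 1L) %/% 2L
  ext <- reflect_pad(x, length(b))
  y <- signal::fftfilt(b, c(ext$x, numeric(delay)))
  y <- y[-seq_len(delay)]
  y[(ext$pad + 1L):(ext$pad + n)]
}

# Windowed-sinc (firwin-style) band-stop design for the power-line notch.
# Tap count follows from the requested transition bandwidth (Hamming window:
# ~3.3 / normalized transition width), forced odd for integer group delay.
design_notch_fir <- function(freq_hz, fs, width_hz = 1, transition_hz = 0.5) {
  nyq <- fs / 2
  if (freq_hz + width_hz >= nyq)
    stop("notch frequency too close to the Nyquist frequency")
  n_taps <- ceiling(3.3 / (transition_hz / fs))
  if (n_taps %% 2L == 0L) n_taps <- n_taps + 1L
  signal::fir1(n_taps - 1L,
               c(freq_hz - width_hz, freq_hz + width_hz) / nyq,
               type = "stop")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop("`", name, "` must be a finite scalar in [", lower, ", ", upper, "]")
  as.numeric(x)
}

# --- Butterworth band-pass in cascaded biquads -------------------------------
#
# Transfer-function (b, a) forms of narrow band-pass designs become
# numerically fragile at audio sample rates (poles cluster near z = 1), so
# band-passes are designed analytically and realized as second-order
# sections: analog Butterworth prototype -> lowpass-to-bandpass transform
# pole by pole -> bilinear transform biquad by biquad.

bilinear_biquad <- function(b_s, a_s, fs) {
  # b_s, a_s: length-3 analog coefficients in descending powers of s
  K <- 2 * fs
  p1 <- c(1, -1)   # (1 - z^-1)
  p0 <- c(1, 1)    # (1 + z^-1)
  conv2 <- function(x, y) convolve(x, rev(y), type = "open")
  basis <- list(conv2(p0, p0), conv2(p1, p0) * K, conv2(p1, p1) * K^2)
  num <- b_s[3] * basis[[1]] + b_s[2] * basis[[2]] + b_s[1] * basis[[3]]
  den <- a_s[3] * basis[[1]] + a_s[2] * basis[[2]] + a_s[1] * basis[[3]]
  list(b = num / den[1], a = den / den[1])
}

#' Design a Butterworth band-pass as second-order sections
#'
#' @param low_hz,high_hz band edges in Hz.
#' @param fs sample rate in Hz.
#' @param order prototype order (the realized band-pass has `2 * order`
#'   poles; quoted pre-reflection when applied forward-backward).
#' @return list of biquads, each a list with `b` and `a` (length 3).
#' @keywords internal
butter_sos_bandpass <- function(low_hz, high_hz, fs, order) {
  nyq <- fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < Nyquist (", nyq, " Hz)")
  warp <- function(f) 2 * fs * tan(pi * f / fs)   # bilinear prewarping
  wl <- warp(low_hz); wh <- warp(high_hz)
  w0sq <- wl * wh
  bw <- wh - wl
  k <- seq_len(order)
  proto <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  sections <- list()
  for (p in proto[Im(proto) > 1e-12]) {
    # complex prototype pair (p, Conj(p)): s^2 - p*bw*s + w0^2 has roots s1,
    # s2; each pairs with its own conjugate (from Conj(p)) into a biquad
    disc <- sqrt(as.complex((p * bw)^2 - 4 * w0sq))
    for (s_pole in c((p * bw + disc) / 2, (p * bw - disc) / 2)) {
      a_s <- c(1, -2 * Re(s_pole), Mod(s_pole)^2)
      sections[[length(sections) + 1L]] <- bilinear_biquad(c(0, bw, 0), a_s, fs)
    }
  }
  if (order %% 2L == 1L) {
    # real prototype pole at s = -1: quadratic s^2 + bw*s + w0^2
    sections[[length(sections) + 1L]] <-
      bilinear_biquad(c(0, bw, 0), c(1, bw, w0sq), fs)
  }
  sections
}

# Zero-phase application of a biquad cascade.
sos_filtfilt <- function(sections, x) {
  for (sec in sections) x <- filtfilt_reflect(sec, x)
  x
}

# Squared magnitude response (dB) of a zero-phase biquad cascade at given
# frequencies; serves as the design-side account of attenuation figures.
sos_response_db <- function(sections, freq_hz, fs) {
  z <- exp(-2i * pi * freq_hz / fs)
  h <- rep(1 + 0i, length(freq_hz))
  for (sec in sections) {
    h <- h * (sec$b[1] + sec$b[2] * z + sec$b[3] * z^2) /
      (sec$a[1] + sec$a[2] * z + sec$a[3] * z^2)
  }
  20 * log10(Mod(h)^2)   # forward-backward squares the magnitude
}
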