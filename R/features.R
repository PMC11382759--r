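#' Speech features for the speech-FFR forward model
#'
#' The cortical speech-FFR is modelled from two per-sample speech features
#' in the band of the speaker's fundamental frequency: the *fundamental
#' waveform* `f_t` (the speech signal band-passed around the f0 range) and
#' the *envelope modulation* `e_t` (the f0-rate amplitude fluctuation of
#' the higher harmonics, extracted through an auditory-periphery style
#' filterbank).  A `stimulus_features` object bundles both features with
#' the f0 track they derive from.
#'
#' @param fundamental numeric vector, the fundamental waveform `f_t`.
#' @param envelope numeric vector, the envelope modulation `e_t`.
#' @param f0 an [f0_track] object (or `NULL`).
#' @param fs sample rate of both features in Hz.
#' @return an object of class `stimulus_features`.
#' @export
stimulus_features <- function(fundamental, envelope, f0 = NULL, fs) {
  if (length(fundamental) != length(envelope))
    stop("fundamental and envelope must have the same length")
  fs <- check_scalar(fs, "fs", lower = 1e-9)
  structure(list(fundamental = as.numeric(fundamental),
                 envelope = as.numeric(envelope),
                 f0 = f0, fs = fs),
            class = "stimulus_features")
}

#' @export
print.stimulus_features <- function(x, ...) {
  cat("<stimulus_features> ", length(x$fundamental), " samples @ ", x$fs,
      " Hz (", round(length(x$fundamental) / x$fs, 2), " s)\n", sep = "")
  invisible(x)
}

#' @export
length.stimulus_features <- function(x) length(x$fundamental)

#' Per-sample fundamental-frequency track
#'
#' @param f0_hz numeric vector of per-sample f0 estimates in Hz.
#' @param voiced logical vector flagging voiced samples.
#' @param fs sample rate in Hz.
#' @return an object of class `f0_track`.
#' @export
f0_track <- function(f0_hz, voiced, fs) {
  if (length(f0_hz) != length(voiced))
    stop("f0_hz and voiced must have the same length")
  structure(list(f0_hz = as.numeric(f0_hz), voiced = as.logical(voiced),
                 fs = check_scalar(fs, "fs", lower = 1e-9)),
            class = "f0_track")
}

#' @export
print.f0_track <- function(x, ...) {
  v <- mean(x$voiced)
  cat("<f0_track> ", length(x$f0_hz), " samples @ ", x$fs, " Hz, ",
      round(100 * v, 1), "% voiced", sep = "")
  if (v > 0)
    cat(", median f0 ", round(stats::median(x$f0_hz[x$voiced]), 1), " Hz", sep = "")
  cat("\n")
  invisible(x)
}

#' Track the fundamental frequency of a speech-like signal
#'
#' A simplified YIN tracker: per frame it evaluates the cumulative-mean
#' normalized difference function (CMNDF), picks the first lag in the
#' candidate range below an absolute threshold (or the global CMNDF
#' minimum), refines it by parabolic interpolation, and flags frames whose
#' best CMNDF value stays above a voicing threshold as unvoiced.  Frame
#' estimates are median-smoothed and interpolated to per-sample resolution.
#' All frame computations are vectorized through FFT cross-correlation.
#'
#' @param waveform mono numeric vector.
#' @param fs sample rate in Hz.
#' @param frame_ms analysis window length in ms (default 40; must span
#'   several periods of `fmin_hz`).
#' @param fmin_hz,fmax_hz f0 search range in Hz (defaults 60 and 140,
#'   bracketing a low-pitched male voice).
#' @param hop_ms frame hop in ms (default 10).
#' @param threshold absolute CMNDF threshold for early lag acceptance
#'   (default 0.1).
#' @param voicing_threshold frames whose best CMNDF value exceeds this are
#'   unvoiced (default 0.35).
#' @return an [f0_track] with one estimate per input sample; estimates are
#'   confined to `[fmin_hz, fmax_hz]`.  All-silent input yields an
#'   all-unvoiced track.
#' @export
extract_f0 <- function(waveform, fs, frame_ms = 40, fmin_hz = 60,
                       fmax_hz = 140, hop_ms = 10, threshold = 0.1,
                       voicing_threshold = 0.35) {
  fs <- check_scalar(fs, "fs", lower = 1e-9)
  if (length(waveform) == 0L) stop("waveform is empty")
  if (!(fmin_hz > 0 && fmin_hz < fmax_hz && fmax_hz < fs / 2))
    stop("need 0 < fmin_hz < fmax_hz < Nyquist")
  n <- length(waveform)
  W <- max(8L, round(frame_ms / 1000 * fs))
  hop <- max(1L, round(hop_ms / 1000 * fs))
  tau_min <- max(2L, floor(fs / fmax_hz))
  tau_max <- ceiling(fs / fmin_hz)
  seg_len <- W + tau_max
  if (n < seg_len)
    stop("waveform too short for the requested frame length and fmin_hz")
  starts <- seq(1L, n - seg_len + 1L, by = hop)
  n_frames <- length(starts)
  idx <- outer(seq_len(seg_len) - 1L, starts, `+`)
  seg <- matrix(waveform[idx], nrow = seg_len)

  # difference function d(tau) = E(0) + E(tau) - 2 C(tau), tau = 0..tau_max
  sq <- rbind(matrix(0, 1L, n_frames), apply(seg^2, 2L, cumsum))
  energy <- sq[(0:tau_max) + W + 1L, , drop = FALSE] -
    sq[(0:tau_max) + 1L, , drop = FALSE]               # E(tau)
  nfft <- stats::nextn(seg_len + W, 2)
  head_w <- seg
  head_w[-seq_len(W), ] <- 0
  A <- stats::mvfft(rbind(seg, matrix(0, nfft - seg_len, n_frames)))
  B <- stats::mvfft(rbind(head_w, matrix(0, nfft - seg_len, n_frames)))
  cc <- Re(stats::mvfft(A * Conj(B), inverse = TRUE)) / nfft
  cross <- cc[1:(tau_max + 1L), , drop = FALSE]        # C(tau)
  d <- matrix(rep(energy[1L, ], each = tau_max + 1L), nrow = tau_max + 1L) +
    energy - 2 * cross
  d[d < 0] <- 0                                        # numerical guard

  # CMNDF: d'(tau) = d(tau) * tau / sum_{j<=tau} d(j)
  csum <- apply(d[-1L, , drop = FALSE], 2L, cumsum)
  dn <- d
  dn[1L, ] <- 1
  denom <- csum
  denom[denom <= 0] <- NA
  dn[-1L, ] <- d[-1L, , drop = FALSE] * (1:tau_max) / denom
  dn[is.na(dn)] <- 1

  f0_frame <- rep(NA_real_, n_frames)
  voiced_frame <- logical(n_frames)
  silent <- energy[1L, ] <= 1e-12 * max(energy[1L, ], 1e-300)
  cand <- tau_min:tau_max
  for (j in seq_len(n_frames)) {
    if (silent[j]) next
    dj <- dn[cand + 1L, j]
    below <- which(dj < threshold)
    pick <- if (length(below)) below[1L] else which.min(dj)
    # descend from the threshold crossing to the local minimum of the CMNDF
    while (pick < length(dj) && dj[pick + 1L] < dj[pick]) pick <- pick + 1L
    tau <- cand[pick]
    if (dn[tau + 1L, j] >= voicing_threshold) next
    # parabolic refinement on the CMNDF around tau
    if (tau > 1L && tau < tau_max) {
      y0 <- dn[tau, j]; y1 <- dn[tau + 1L, j]; y2 <- dn[tau + 2L, j]
      den <- y0 - 2 * y1 + y2
      if (is.finite(den) && abs(den) > 1e-12)
        tau <- tau + max(-0.5, min(0.5, 0.5 * (y0 - y2) / den))
    }
    f0_frame[j] <- fs / tau
    voiced_frame[j] <- TRUE
  }

  if (any(voiced_frame)) {
    vi <- which(voiced_frame)
    if (length(vi) >= 3L)
      f0_frame[vi] <- stats::runmed(f0_frame[vi], k = min(5L, length(vi) - (1 - length(vi) %% 2)))
    f0_frame <- pmin(pmax(f0_frame, fmin_hz), fmax_hz)
    centers <- starts + W / 2
    f0_samp <- stats::approx(centers[vi], f0_frame[vi], xout = seq_len(n),
                             rule = 2)$y
    voiced_samp <- stats::approx(centers, as.numeric(voiced_frame),
                                 xout = seq_len(n), method = "constant",
                                 rule = 2)$y >= 0.5
  } else {
    f0_samp <- rep(NA_real_, n)
    voiced_samp <- rep(FALSE, n)
  }
  f0_track(f0_samp, voiced_samp, fs)
}

#' Fundamental waveform of a speech signal
#'
#' Band-passes the speech signal around the speaker's fundamental-frequency
#' range with a zero-phase fourth-order Butterworth filter (defaults
#' 65-120 Hz), realized as cascaded second-order sections and applied
#' forward-backward.
#'
#' @param waveform mono numeric vector.
#' @param fs sample rate in Hz (must exceed twice the upper band edge).
#' @param low_hz,high_hz band edges in Hz (defaults 65 and 120).
#' @param order prototype filter order (default 4).
#' @return numeric vector `f_t`, same length as `waveform`.
#' @export
fundamental_waveform <- function(waveform, fs, low_hz = 65, high_hz = 120,
                                 order = 4) {
  fs <- check_scalar(fs, "fs", lower = 2 * high_hz + 1e-9)
  sos <- butter_sos_bandpass(low_hz, high_hz, fs, order)
  sos_filtfilt(sos, as.numeric(waveform))
}

#' Constant-Q filterbank specification
#'
#' Third-octave-spaced band centres between `f_lo` and `f_hi` (default:
#' 150 Hz up to `min(4000, 0.45 * fs)`), each band a second-order
#' Butterworth band-pass of relative bandwidth `1/q`.
#'
#' @param fs sample rate in Hz.
#' @param f_lo lowest centre frequency in Hz (above the f0 band).
#' @param f_hi highest centre frequency in Hz (`NULL`: `min(4000, 0.45 fs)`).
#' @param q quality factor, centre / bandwidth (default 4).
#' @param compression power-law compression exponent applied to band
#'   envelopes (default 0.3).
#' @return list with fields `centers_hz`, `q`, `compression`.
#' @export
filterbank_spec <- function(fs, f_lo = 150, f_hi = NULL, q = 4,
                            compression = 0.3) {
  f_hi <- f_hi %||% min(4000, 0.45 * fs)
  if (f_lo >= f_hi) stop("filterbank requires f_lo < f_hi < Nyquist")
  n_bands <- floor(log(f_hi / f_lo) / log(2) * 3) + 1L
  centers <- f_lo * 2^((seq_len(n_bands) - 1L) / 3)
  list(centers_hz = centers, q = q, compression = compression)
}

#' Envelope modulation of the higher harmonics
#'
#' Auditory-periphery style extraction of the f0-rate amplitude
#' fluctuation carried by the harmonics above the fundamental: the signal
#' is split into constant-Q bands, each band's amplitude envelope is taken
#' as the analytic-signal magnitude and compressed by a power law, the
#' bands are summed with equal weight, and the sum is band-passed to the
#' f0 range (zero-phase fourth-order Butterworth, defaults 70-120 Hz).
#'
#' @param waveform mono numeric vector.
#' @param fs sample rate in Hz.
#' @param spec filterbank specification from [filterbank_spec()] (default:
#'   `filterbank_spec(fs)`).
#' @param low_hz,high_hz final band-pass edges in Hz (defaults 70 and 120).
#' @return numeric vector `e_t`, same length as `waveform`.
#' @export
envelope_modulation <- function(waveform, fs, spec = NULL, low_hz = 70,
                                high_hz = 120) {
  fs <- check_scalar(fs, "fs", lower = 2 * high_hz + 1e-9)
  spec <- spec %||% filterbank_spec(fs)
  if (length(spec$centers_hz) == 0L) stop("empty filterbank")
  if (any(spec$centers_hz <= high_hz) || any(spec$centers_hz >= 0.5 * fs))
    stop("filterbank centres must lie above the f0 band and below Nyquist")
  x <- as.numeric(waveform)
  acc <- numeric(length(x))
  for (cf in spec$centers_hz) {
    half_bw <- cf / (2 * spec$q)
    sos <- butter_sos_bandpass(cf - half_bw, min(cf + half_bw, 0.49 * fs),
                               fs, 2)
    band <- sos_filtfilt(sos, x)
    env <- Mod(analytic_signal(band))^spec$compression
    acc <- acc + env
  }
  acc <- acc / length(spec$centers_hz)
  sos_out <- butter_sos_bandpass(low_hz, high_hz, fs, 4)
  sos_filtfilt(sos_out, acc)
}

#' Pearson correlation between the two speech features
#'
#' Used to verify that the fundamental waveform and the envelope modulation
#' capture essentially unrelated aspects of the stimulus.
#'
#' @param f,e numeric vectors of equal length (>= 3).
#' @return list with `r` and `p` (two-sided).  Constant input yields
#'   `r = NA` with a warning.
#' @export
feature_correlation <- function(f, e) {
  if (length(f) != length(e)) stop("features must have the same length")
  if (length(f) < 3L) stop("need at least 3 samples")
  if (stats::sd(f) == 0 || stats::sd(e) == 0) {
    warning("correlation undefined for constant input")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(f, e, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Extract both speech features at a working rate
#'
#' Convenience front end used by the pipeline: computes the f0 track, the
#' fundamental waveform, and the envelope modulation from audio at its
#' native rate, then Fourier-resamples both features (and the f0 track) to
#' `out_rate`, the rate of the neural recording.  Both features are
#' rescaled to a common reference RMS (default 0.02, the order of the
#' f0-band RMS of full-scale speech audio, about -20 dB re full scale):
#' the auditory-model units of the envelope modulation are arbitrary, and
#' a fixed reference scale puts the two features and the fixed ridge
#' penalty `lambda = 1` on the footing in which that penalty is
#' near-optimal and suppresses the diffuse coefficient spread of
#' misaligned (noise-model) fits.
#'
#' @param waveform mono numeric vector (or a list with `samples` and `fs`
#'   as returned by [read_wav()]).
#' @param fs sample rate in Hz (ignored if `waveform` carries its own).
#' @param out_rate target feature rate in Hz (default 1000).
#' @param f0_band f0 search range for the tracker (default `c(60, 140)`).
#' @param f0 optionally, an externally supplied [f0_track] to store in
#'   place of running the tracker.
#' @param spec filterbank specification for [envelope_modulation()].
#' @param reference_rms common output RMS of both features (default 0.02).
#' @return a [stimulus_features] object at `out_rate`.
#' @export
extract_stimulus_features <- function(waveform, fs, out_rate = 1000,
                                      f0_band = c(60, 140), f0 = NULL,
                                      spec = NULL, reference_rms = 0.02) {
  if (is.list(waveform)) {
    fs <- waveform$fs
    waveform <- waveform$samples
  }
  fs <- check_scalar(fs, "fs", lower = 2 * 120 + 1e-9)
  f_t <- fundamental_waveform(waveform, fs)
  e_t <- envelope_modulation(waveform, fs, spec = spec)
  if (is.null(f0))
    f0 <- extract_f0(waveform, fs, fmin_hz = f0_band[1L], fmax_hz = f0_band[2L])
  f_t <- (f_t - mean(f_t)) / max(stats::sd(f_t), 1e-300) * reference_rms
  e_t <- (e_t - mean(e_t)) / max(stats::sd(e_t), 1e-300) * reference_rms
  n_out <- round(length(waveform) / fs * out_rate)
  if (out_rate != fs) {
    f_t <- fft_resample(f_t, n_out)
    e_t <- fft_resample(e_t, n_out)
    t_out <- (seq_len(n_out) - 1L) / out_rate
    t_in <- (seq_along(f0$f0_hz) - 1L) / f0$fs
    if (any(f0$voiced)) {
      f0_hz <- stats::approx(t_in, f0$f0_hz, xout = t_out, rule = 2)$y
    } else {
      f0_hz <- rep(NA_real_, n_out)
    }
    voiced <- stats::approx(t_in, as.numeric(f0$voiced), xout = t_out,
                            method = "constant", rule = 2)$y >= 0.5
    f0 <- f0_track(f0_hz, voiced, out_rate)
  }
  stimulus_features(f_t, e_t, f0, out_rate)
}
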