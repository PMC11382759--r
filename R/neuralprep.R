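#' Continuous neural recording
#'
#' Container for a multichannel, uniformly sampled neural time series
#' (sensor- or source-level), together with the metadata the pipeline
#' needs: the sample rate, the stimulus alignment offset, per-channel
#' roles, and a provenance log of the conditioning steps applied.
#'
#' @param samples numeric matrix, channels x time (a vector is treated as
#'   one channel).
#' @param fs sample rate in Hz.
#' @param alignment_offset_ms acoustic lead of the stimulus relative to the
#'   recording, in ms (default 6, the delay of the sound-delivery tubes).
#' @param channel_roles character vector, one of `"sensor"` or
#'   `"source-point"` per channel (recycled).
#' @return an object of class `neural_recording`.  Conditioning operations
#'   append to its `provenance` log and raise `edge_contaminated_ms`, the
#'   length of the leading/trailing stretch that filter transients may have
#'   touched.
#' @export
neural_recording <- function(samples, fs, alignment_offset_ms = 6,
                             channel_roles = "sensor") {
  if (is.vector(samples)) samples <- matrix(samples, nrow = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("samples must be a numeric channels x time matrix")
  fs <- check_scalar(fs, "fs", lower = 1e-9)
  alignment_offset_ms <- check_scalar(alignment_offset_ms, "alignment_offset_ms")
  channel_roles <- rep_len(as.character(channel_roles), nrow(samples))
  structure(list(samples = samples, fs = fs,
                 alignment_offset_ms = alignment_offset_ms,
                 channel_roles = channel_roles,
                 provenance = character(),
                 edge_contaminated_ms = 0),
            class = "neural_recording")
}

#' @export
print.neural_recording <- function(x, ...) {
  cat("<neural_recording> ", nrow(x$samples), " channel(s) x ",
      ncol(x$samples), " samples @ ", x$fs, " Hz\n", sep = "")
  if (length(x$provenance))
    cat("  applied: ", paste(x$provenance, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.neural_recording <- function(x) dim(x$samples)

log_step <- function(rec, step, edge_ms = 100) {
  rec$provenance <- c(rec$provenance, step)
  # zero-phase filtering spreads edge transients into the record; the first
  # and last stretch are flagged as potentially edge-contaminated
  rec$edge_contaminated_ms <- max(rec$edge_contaminated_ms, edge_ms)
  rec
}

#' Power-line notch filter
#'
#' Removes a narrow band around `freq_hz` with a windowed-sinc (firwin
#' style) linear-phase FIR band-stop, applied with group-delay
#' compensation so the net filter is zero-phase.
#'
#' @param recording a [neural_recording].
#' @param freq_hz notch centre in Hz (default 50).
#' @param width_hz half-width of the stop band in Hz (default 1).
#' @param transition_hz transition bandwidth in Hz governing the filter
#'   length (default 0.5).
#' @return the filtered [neural_recording].
#' @export
notch <- function(recording, freq_hz = 50, width_hz = 1, transition_hz = 0.5) {
  stopifnot(inherits(recording, "neural_recording"))
  if (freq_hz >= recording$fs / 2) stop("notch frequency must be below Nyquist")
  b <- design_notch_fir(freq_hz, recording$fs, width_hz, transition_hz)
  recording$samples <- t(apply(recording$samples, 1L, fir_filter_zero_phase,
                               b = b))
  log_step(recording, sprintf("notch(%g Hz)", freq_hz))
}

#' Down-sample a recording
#'
#' Fourier-domain resampling to a lower rate; anti-aliasing is implicit in
#' the spectral truncation.  Upsampling is outside the contract.
#'
#' @param recording a [neural_recording].
#' @param target_rate_hz new sample rate in Hz, at most the current rate.
#' @return the resampled [neural_recording]; the duration is preserved to
#'   within one sample.
#' @export
resample_recording <- function(recording, target_rate_hz) {
  stopifnot(inherits(recording, "neural_recording"))
  target_rate_hz <- check_scalar(target_rate_hz, "target_rate_hz", lower = 1e-9)
  if (target_rate_hz > recording$fs)
    stop("up-sampling is not supported; target rate exceeds current rate")
  if (target_rate_hz == recording$fs) return(recording)
  n_out <- round(ncol(recording$samples) / recording$fs * target_rate_hz)
  recording$samples <- t(apply(recording$samples, 1L, fft_resample,
                               n_out = n_out))
  recording$fs <- target_rate_hz
  log_step(recording, sprintf("resample(%g Hz)", target_rate_hz))
}

#' Band-pass to the frequency-following-response band
#'
#' Zero-phase Butterworth band-pass (default second order, 70-120 Hz,
#' applied forward-backward) selecting the band of the speaker's
#' fundamental frequency in the neural recording.
#'
#' @param recording a [neural_recording].
#' @param low_hz,high_hz band edges in Hz (defaults 70 and 120).
#' @param order prototype filter order (default 2).
#' @return the filtered [neural_recording].
#' @export
ffr_bandpass <- function(recording, low_hz = 70, high_hz = 120, order = 2) {
  stopifnot(inherits(recording, "neural_recording"))
  sos <- butter_sos_bandpass(low_hz, high_hz, recording$fs, order)
  recording$samples <- t(apply(recording$samples, 1L, function(ch)
    sos_filtfilt(sos, ch)))
  log_step(recording, sprintf("bandpass(%g-%g Hz)", low_hz, high_hz))
}

#' Align stimulus features with a neural recording
#'
#' Delays the feature streams by the acoustic transmission delay of the
#' sound-delivery tubes (default: the recording's `alignment_offset_ms`)
#' and trims recording and features to their common support.
#'
#' @param recording a [neural_recording].
#' @param features a [stimulus_features] object at the same sample rate.
#' @param tube_delay_ms acoustic delay in ms; positive values delay the
#'   features relative to the recording.  Default: the offset stored in the
#'   recording.
#' @return list with elements `recording` and `features`, trimmed to equal
#'   length.
#' @export
align_features <- function(recording, features,
                           tube_delay_ms = recording$alignment_offset_ms) {
  stopifnot(inherits(recording, "neural_recording"),
            inherits(features, "stimulus_features"))
  if (abs(recording$fs - features$fs) > 1e-9)
    stop("recording and features must share a sample rate")
  shift <- round(tube_delay_ms / 1000 * recording$fs)
  n_feat <- length(features$fundamental)
  n_rec <- ncol(recording$samples)
  if (abs(shift) >= min(n_feat, n_rec))
    stop("alignment delay exceeds the signal length")
  shift_vec <- function(x) {
    if (shift > 0) c(numeric(shift), x)[seq_len(n_feat)]
    else if (shift < 0) c(x[(-shift + 1L):n_feat], numeric(-shift))
    else x
  }
  f <- shift_vec(features$fundamental)
  e <- shift_vec(features$envelope)
  n <- min(length(f), n_rec)
  recording$samples <- recording$samples[, seq_len(n), drop = FALSE]
  recording$alignment_offset_ms <- 0
  recording <- log_step(recording, sprintf("align(%g ms)", tube_delay_ms))
  f0 <- features$f0
  if (!is.null(f0)) {
    f0_hz <- shift_vec(c(f0$f0_hz, numeric(max(0, n_feat - length(f0$f0_hz)))))
    voiced <- shift_vec(as.numeric(f0$voiced)) >= 0.5
    f0 <- f0_track(f0_hz[seq_len(n)], voiced[seq_len(n)], features$fs)
  }
  list(recording = recording,
       features = stimulus_features(f[seq_len(n)], e[seq_len(n)], f0,
                                    features$fs))
}
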