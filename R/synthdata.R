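# Synthetic stimuli, neural responses with known ground truth, and cohorts.
# Every downstream stage (feature extraction, TRF estimation, significance
# testing, attention and cohort statistics) is validated by recovering the
# parameters this module planted.

# Evaluate code under a temporary RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Gabor-shaped TRF kernel
#'
#' The canonical ground-truth kernel shape: a Gaussian envelope centred at
#' the peak latency carrying an oscillation at the stimulus fundamental
#' frequency, mirroring the oscillatory TRFs the forward model recovers.
#'
#' @param axis a [lag_axis].
#' @param peak_ms envelope peak latency in ms (default 35).
#' @param sigma_ms Gaussian width in ms (default 6).
#' @param freq_hz carrier frequency in Hz (default 95, mid f0 band).
#' @param amplitude peak amplitude (default 1).
#' @param phase carrier phase at the peak in radians (default 0).
#' @return numeric vector over the lag axis.
#' @export
gabor_kernel <- function(axis = lag_axis(), peak_ms = 35, sigma_ms = 6,
                         freq_hz = 95, amplitude = 1, phase = 0) {
  tau <- axis$lags_ms
  amplitude * exp(-(tau - peak_ms)^2 / (2 * sigma_ms^2)) *
    cos(2 * pi * freq_hz * (tau - peak_ms) / 1000 + phase)
}

#' Ground truth for synthetic neural responses
#'
#' Bundles the generating TRF kernels for both speech features with the
#' attention gain and the noise level, defining everything the generator
#' needs and everything the recovery tests check against.
#'
#' @param axis a [lag_axis] (shared with later estimation).
#' @param kernel_alpha,kernel_beta generating kernels over `axis` for the
#'   fundamental waveform and the envelope modulation.  Defaults: Gabor
#'   kernels peaking at `peak_latency_ms`, the envelope-modulation kernel
#'   at 0.7 relative amplitude.
#' @param peak_latency_ms envelope peak latency of the default kernels in
#'   ms (default 35).
#' @param attention_gain multiplicative gain of the attended over the
#'   ignored response, >= 1 (default 1.5).
#' @param noise_sd additive noise standard deviation in response units;
#'   alternatively give `snr_db` and leave `noise_sd = NULL`.
#' @param snr_db signal-to-noise ratio in dB of the ignored-condition clean
#'   signal over the noise (used when `noise_sd` is `NULL`; default 0).
#' @param noise_exponent spectral exponent of the noise: 0 = white,
#'   1 = 1/f (default 0).
#' @param band_limit_hz band to which the default kernels are confined
#'   (default `c(70, 120)`, the analysis band; `NULL` disables).  Both the
#'   speech features and the neural recordings are restricted to the f0
#'   band, so kernel components outside it are invisible to any analysis;
#'   a generative kernel living in the band is the physically meaningful
#'   ground truth.  User-supplied kernels are taken as-is.
#' @param seed integer seed for the noise draws.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(axis = lag_axis(), kernel_alpha = NULL,
                         kernel_beta = NULL, peak_latency_ms = 35,
                         attention_gain = 1.5, noise_sd = NULL, snr_db = 0,
                         noise_exponent = 0, band_limit_hz = c(70, 120),
                         seed = 1L) {
  if (attention_gain < 1) stop("attention_gain must be >= 1")
  band_limit <- function(kern) {
    if (is.null(band_limit_hz)) return(kern)
    fs_lag <- 1000 / axis$step_ms
    sos_filtfilt(butter_sos_bandpass(band_limit_hz[1L], band_limit_hz[2L],
                                     fs_lag, 2), kern)
  }
  kernel_alpha <- kernel_alpha %||%
    band_limit(gabor_kernel(axis, peak_ms = peak_latency_ms))
  kernel_beta <- kernel_beta %||%
    band_limit(gabor_kernel(axis, peak_ms = peak_latency_ms, amplitude = 0.7))
  if (length(kernel_alpha) != axis$n_lags || length(kernel_beta) != axis$n_lags)
    stop("kernels must span the lag axis")
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(lag_axis = axis, kernel_alpha = kernel_alpha,
                 kernel_beta = kernel_beta, peak_latency_ms = peak_latency_ms,
                 attention_gain = attention_gain, noise_sd = noise_sd,
                 snr_db = snr_db, noise_exponent = noise_exponent,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Generate a smoothly wandering f0 trajectory
#'
#' Low-pass-filtered Gaussian noise squashed into the requested frequency
#' range by a tanh map, emulating the slow pitch drift of a speaker whose
#' fundamental stays within a fixed band.
#'
#' @param duration_s trajectory length in seconds.
#' @param f0_range_hz length-2 interval in Hz the trajectory is confined to
#'   (default `c(70, 120)`, a low-pitched male voice).
#' @param wander_rate_hz low-pass cut-off of the drift in Hz (default 0.5,
#'   a slow prosodic pitch drift); 0 yields a constant trajectory at the
#'   interval midpoint.
#' @param seed integer seed.
#' @param fs sample rate in Hz (default 8000).
#' @return an [f0_track] (all samples voiced).
#' @export
gen_f0_trajectory <- function(duration_s, f0_range_hz = c(70, 120),
                              wander_rate_hz = 0.5, seed = 1L, fs = 8000) {
  duration_s <- check_scalar(duration_s, "duration_s", lower = 1e-9)
  if (length(f0_range_hz) != 2L || f0_range_hz[1L] >= f0_range_hz[2L])
    stop("f0_range_hz must be an increasing interval")
  if (f0_range_hz[2L] >= fs / 2) stop("f0 range must lie below Nyquist")
  if (wander_rate_hz < 0) stop("wander_rate_hz must be >= 0")
  n <- round(duration_s * fs)
  mid <- mean(f0_range_hz)
  halfwidth <- diff(f0_range_hz) / 2
  if (wander_rate_hz == 0) return(f0_track(rep(mid, n), rep(TRUE, n), fs))
  x <- with_seed(seed, stats::rnorm(n))
  filt <- butter_lowpass(min(wander_rate_hz, 0.45 * fs), fs, 2)
  x <- filtfilt_reflect(filt, x)
  x <- x / max(stats::sd(x), 1e-12)
  f0_track(mid + halfwidth * tanh(x), rep(TRUE, n), fs)
}

#' Generate a harmonic voice following an f0 trajectory
#'
#' A harmonic complex whose instantaneous fundamental follows the given f0
#' track.  Harmonic amplitudes decay as 1/k.  Harmonics above the
#' fundamental carry an amplitude modulation at the f0 rate (depth 0.5)
#' whose phase relative to the glottal cycle drifts slowly and randomly,
#' so that the envelope modulation of the higher harmonics decorrelates
#' from the fundamental waveform over long stretches, as in natural
#' speech.
#'
#' @param f0 an [f0_track] from [gen_f0_trajectory()] or [extract_f0()].
#' @param n_harmonics number of harmonics (>= 1); harmonics reaching the
#'   Nyquist frequency are dropped with a warning.
#' @param fs output sample rate in Hz (default: the track's rate).
#' @param seed integer seed for the harmonic phases and modulation drift.
#' @param mod_depth amplitude-modulation depth of the higher harmonics
#'   (default 0.5).
#' @param syllable_rate_hz rate of the speech-like syllabic energy
#'   fluctuation imposed on the whole voice (default 4 Hz, the canonical
#'   syllable rate; 0 disables).  This slow amplitude structure is what
#'   makes time-reversed features a proper null: reversing the stimulus
#'   misaligns the energy bursts with the response.
#' @param syllable_floor amplitude floor of the syllabic envelope relative
#'   to its peaks (default 0.1).
#' @return numeric waveform, peak-normalized to 0.9.
#' @export
gen_voice <- function(f0, n_harmonics = 5L, fs = f0$fs, seed = 1L,
                      mod_depth = 0.5, syllable_rate_hz = 4,
                      syllable_floor = 0.1) {
  stopifnot(inherits(f0, "f0_track"))
  if (n_harmonics < 1L) stop("n_harmonics must be >= 1")
  f0_hz <- f0$f0_hz
  if (fs != f0$fs) {
    t_out <- (seq_len(round(length(f0_hz) / f0$fs * fs)) - 1L) / fs
    f0_hz <- stats::approx((seq_along(f0_hz) - 1L) / f0$fs, f0_hz,
                           xout = t_out, rule = 2)$y
  }
  f0_hz[!is.finite(f0_hz)] <- stats::median(f0_hz[is.finite(f0_hz)])
  n <- length(f0_hz)
  keep <- which(seq_len(n_harmonics) * max(f0_hz) < fs / 2)
  if (length(keep) < n_harmonics)
    warning("dropping harmonics above the Nyquist frequency (keeping ",
            length(keep), " of ", n_harmonics, ")")
  if (!length(keep)) stop("no harmonic fits below the Nyquist frequency")
  phase <- 2 * pi * cumsum(f0_hz) / fs
  wave <- numeric(n)
  with_seed(seed, {
    # vocal-tract variability decoheres the harmonics from the glottal
    # cycle: carrier phases drift gently (SD pi/2 at ~1 Hz, slow enough to
    # leave the composite waveform's periodicity trackable) while the
    # amplitude-modulation phase drifts at phoneme-like rate (SD pi at
    # ~3 Hz), which carries no pitch information
    slow_drift <- function(scale, rate_hz) {
      filt <- butter_lowpass(min(rate_hz, 0.45 * fs), fs, 2)
      d <- filtfilt_reflect(filt, stats::rnorm(n))
      d / max(stats::sd(d), 1e-12) * scale
    }
    for (k in keep) {
      phi_k <- stats::runif(1, 0, 2 * pi)
      if (k == 1L) {
        wave <- wave + sin(phase + phi_k)
      } else {
        # harmonics above the fundamental drift in phase relative to the
        # glottal cycle, so their mutual beats and their f0-rate amplitude
        # modulation decohere from the fundamental over long stretches, as
        # in natural speech
        theta <- slow_drift(pi / 2, 1)
        psi <- stats::runif(1, 0, 2 * pi) + slow_drift(pi, 3)
        amp <- 1 + mod_depth * sin(phase + psi)
        wave <- wave + (amp / k) * sin(k * phase + phi_k + theta)
      }
    }
    if (syllable_rate_hz > 0) {
      syl_filt <- butter_lowpass(min(syllable_rate_hz, 0.45 * fs), fs, 2)
      z <- filtfilt_reflect(syl_filt, stats::rnorm(n))
      z <- z / max(stats::sd(z), 1e-12)
      syl <- syllable_floor + (1 - syllable_floor) * (0.5 + 0.5 * tanh(1.5 * z))
      wave <- wave * syl
    }
  })
  wave / max(abs(wave)) * 0.9
}

# Clean (noise-free, unit-gain) response underlying a synthetic recording.
clean_response <- function(features, truth, design = NULL) {
  design <- design %||% build_design(features, truth$lag_axis)
  if (nrow(design) <= truth$lag_axis$n_lags)
    stop("signal shorter than the kernel support")
  drop(design %*% c(truth$kernel_alpha, truth$kernel_beta))
}

# Gaussian noise with spectral exponent `expo` (0 = white, 1 = 1/f).
shaped_noise <- function(n, sd, expo) {
  z <- stats::rnorm(n)
  if (expo == 0 || sd == 0) return(z * sd)
  Z <- stats::fft(z)
  freq <- c(1, seq_len(n - 1L))
  freq <- pmin(freq, n - freq + 1L)
  Z <- Z / freq^(expo / 2)
  z <- Re(stats::fft(Z, inverse = TRUE)) / n
  z / stats::sd(z) * sd
}

#' Generate a synthetic neural response
#'
#' Convolves the two speech features with the ground-truth kernels over
#' the lag axis (the generative reading of the forward model), scales by
#' the attention gain when the speaker is attended, and adds independent
#' noise per channel.  When the truth specifies `snr_db` instead of
#' `noise_sd`, the noise SD is set relative to the ignored-condition
#' (unit-gain) clean signal, so both attention conditions see the same
#' absolute noise level.
#'
#' @param features a [stimulus_features] object.
#' @param truth a [ground_truth].
#' @param attended logical: is the speaker attended?
#' @param n_channels number of channels (independent noise draws).
#' @return a [neural_recording] with zero alignment offset and channel
#'   role `"source-point"`.
#' @export
gen_neural_response <- function(features, truth, attended = TRUE,
                                n_channels = 1L) {
  stopifnot(inherits(features, "stimulus_features"),
            inherits(truth, "ground_truth"))
  clean <- clean_response(features, truth)
  g <- if (attended) truth$attention_gain else 1
  noise_sd <- truth$noise_sd %||%
    (stats::sd(clean) * 10^(-truth$snr_db / 20))
  n <- length(clean)
  samples <- with_seed(truth$seed + as.integer(attended), {
    t(vapply(seq_len(n_channels), function(ch)
      g * clean + shaped_noise(n, noise_sd, truth$noise_exponent),
      numeric(n)))
  })
  neural_recording(samples, features$fs, alignment_offset_ms = 0,
                   channel_roles = "source-point")
}

#' Generate a synthetic participant cohort
#'
#' Draws musical-training profiles that satisfy the musician and
#' non-musician criteria for the first two groups and violate exactly one
#' musician criterion for the neutral group, plus a behavioral score from
#' binomial answering of the comprehension questions and per-subject
#' neural-response parameters (TRF amplitude scale and latency shift).
#'
#' @param n_musicians,n_nonmusicians,n_neutral group sizes (>= 0); the
#'   study cohort corresponds to (18, 25, 9).
#' @param seed integer seed.
#' @param p_correct per-question success probability of the binomial
#'   behavioral model (default 0.8; 0.25 is chance on four options).
#' @param n_questions number of comprehension questions (default 30).
#' @param amplitude_sd SD of the log-normal inter-subject TRF amplitude
#'   scale (default 0.2; the inter-subject variability is a free
#'   parameter, not an estimated quantity).
#' @param latency_sd_ms SD of the inter-subject peak-latency shift in ms
#'   (default 1).
#' @return data.frame with one row per participant: training attributes,
#'   intended `group`, `percent_correct`, `kernel_scale`,
#'   `latency_shift_ms`.
#' @export
gen_cohort <- function(n_musicians = 18L, n_nonmusicians = 25L,
                       n_neutral = 9L, seed = 1L, p_correct = 0.8,
                       n_questions = 30L, amplitude_sd = 0.2,
                       latency_sd_ms = 1) {
  if (any(c(n_musicians, n_nonmusicians, n_neutral) < 0))
    stop("group sizes must be >= 0")
  n <- n_musicians + n_nonmusicians + n_neutral
  empty <- data.frame(id = character(), group = character(),
                      starting_age_years = numeric(),
                      total_training_years = numeric(),
                      currently_training = logical(),
                      hours_per_week = numeric(),
                      n_instruments_lifetime = integer(),
                      percent_correct = numeric(), kernel_scale = numeric(),
                      latency_shift_ms = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  with_seed(seed, {
    rows <- vector("list", n)
    i <- 0L
    for (g in seq_len(n_musicians)) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        group = "musician",
        starting_age_years = sample(4:7, 1L),
        total_training_years = round(stats::runif(1, 10, 20), 1),
        currently_training = TRUE,
        hours_per_week = round(stats::runif(1, 1, 25), 1),
        n_instruments_lifetime = sample(1:4, 1L))
    }
    for (g in seq_len(n_nonmusicians)) {
      i <- i + 1L
      never <- stats::runif(1) < 0.6     # 15 of 25 never played
      rows[[i]] <- if (never) data.frame(
        group = "non-musician", starting_age_years = NA_real_,
        total_training_years = 0, currently_training = FALSE,
        hours_per_week = 0, n_instruments_lifetime = 0L)
      else data.frame(
        group = "non-musician",
        starting_age_years = sample(8:15, 1L),
        total_training_years = round(stats::runif(1, 0.5, 3), 1),
        currently_training = FALSE, hours_per_week = 0,
        n_instruments_lifetime = sample(1:2, 1L))
    }
    for (g in seq_len(n_neutral)) {
      i <- i + 1L
      kind <- sample(3L, 1L)
      rows[[i]] <- switch(kind,
        # early start, long training, but lapsed
        data.frame(group = "neutral", starting_age_years = sample(4:7, 1L),
                   total_training_years = round(stats::runif(1, 10, 15), 1),
                   currently_training = FALSE, hours_per_week = 0,
                   n_instruments_lifetime = sample(1:3, 1L)),
        # early start, still training, but short total
        data.frame(group = "neutral", starting_age_years = sample(4:7, 1L),
                   total_training_years = round(stats::runif(1, 4, 9), 1),
                   currently_training = TRUE,
                   hours_per_week = round(stats::runif(1, 1, 10), 1),
                   n_instruments_lifetime = sample(1:3, 1L)),
        # late start, long and current training
        data.frame(group = "neutral", starting_age_years = sample(8:12, 1L),
                   total_training_years = round(stats::runif(1, 10, 18), 1),
                   currently_training = TRUE,
                   hours_per_week = round(stats::runif(1, 1, 10), 1),
                   n_instruments_lifetime = sample(1:3, 1L)))
    }
    cohort <- do.call(rbind, rows)
    cohort$id <- sprintf("S%02d", seq_len(n))
    cohort$percent_correct <-
      100 * stats::rbinom(n, n_questions, p_correct) / n_questions
    cohort$kernel_scale <- exp(stats::rnorm(n, 0, amplitude_sd))
    cohort$latency_shift_ms <- round(stats::rnorm(n, 0, latency_sd_ms))
    cohort[, c("id", "group", "starting_age_years", "total_training_years",
               "currently_training", "hours_per_week",
               "n_instruments_lifetime", "percent_correct", "kernel_scale",
               "latency_shift_ms")]
  })
}
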