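test_that("f0 tracker follows pure tones and drifting harmonic complexes", {
  fs <- 8000
  tone <- make_tone(100, fs, 5)
  tr <- extract_f0(tone, fs)
  expect_true(mean(tr$voiced) > 0.99)
  expect_lt(max(abs(tr$f0_hz[tr$voiced] - 100)), 1)

  # harmonic complex drifting 80 -> 110 Hz
  n <- 5 * fs + 1
  f0d <- seq(80, 110, length.out = n)
  ph <- 2 * pi * cumsum(f0d) / fs
  x <- sin(ph) + 0.5 * sin(2 * ph) + 0.33 * sin(3 * ph)
  tr2 <- extract_f0(x, fs)
  expect_lt(max(abs(tr2$f0_hz - f0d)[tr2$voiced]), 2)

  # oracle: brute-force autocorrelation peak on individual frames
  acf_peak_f0 <- function(seg) {
    lags <- 60:120
    r <- vapply(lags, function(l)
      sum(seg[1:(length(seg) - l)] * seg[(1 + l):length(seg)]), numeric(1))
    fs / lags[which.max(r)]
  }
  for (start in c(8000, 24000)) {
    seg <- x[start:(start + 999)]
    expect_lt(abs(acf_peak_f0(seg) - tr2$f0_hz[start + 500]), 3)
  }
})

test_that("aperiodic and silent input is flagged unvoiced", {
  fs <- 8000
  set.seed(5)
  noise <- rnorm(2 * fs)
  tr <- extract_f0(noise, fs)
  expect_gt(mean(!tr$voiced), 0.5)

  silent <- numeric(fs)
  tr0 <- extract_f0(silent, fs)
  expect_true(all(!tr0$voiced))
  expect_true(all(is.na(tr0$f0_hz)))

  expect_error(extract_f0(numeric(0), fs), "empty")
  expect_error(extract_f0(noise, fs, fmin_hz = 140, fmax_hz = 60), "fmin")
})

test_that("fundamental waveform band-pass matches its design response", {
  fs <- 1000
  # oracle: magnitude response of the designed Butterworth, squared for the
  # forward-backward application
  ba <- signal::butter(4, c(65, 120) / (fs / 2), "pass")
  resp_db <- function(f) {
    z <- exp(-2i * pi * f / fs)
    k <- seq_along(ba$b) - 1
    2 * 20 * log10(Mod(sum(ba$b * z^k) / sum(ba$a * z^k)))
  }
  mid <- 3001:7000
  x100 <- make_tone(100, fs, 10)
  y100 <- fundamental_waveform(x100, fs)
  gain100 <- 20 * log10(sqrt(mean(y100[mid]^2) / mean(x100[mid]^2)))
  expect_gt(gain100, -1)                      # passband centre
  expect_lt(abs(gain100 - resp_db(100)), 0.5) # matches the design

  x300 <- make_tone(300, fs, 10)
  y300 <- fundamental_waveform(x300, fs)
  gain300 <- 20 * log10(sqrt(mean(y300[mid]^2) / mean(x300[mid]^2)))
  expect_lt(resp_db(300), -20)                # the design promises > 20 dB
  expect_lt(gain300, -20)                     # the implementation delivers it
  expect_error(fundamental_waveform(x100, 200), "fs")
})

test_that("zero-phase filtering commutes with time reversal", {
  fs <- 1000
  set.seed(7)
  x <- rnorm(4000)
  y <- fundamental_waveform(x, fs)
  y_rev <- rev(fundamental_waveform(rev(x), fs))
  # agreement away from the reflection-padded edges
  interior <- 501:3500
  expect_lt(max(abs(y - y_rev)[interior]), 1e-6 * stats::sd(y))
})

test_that("envelope modulation demodulates f0-rate amplitude fluctuation", {
  fs <- 8000
  t <- seq(0, 10, by = 1 / fs)
  am <- (1 + sin(2 * pi * 100 * t)) * sin(2 * pi * 300 * t)
  e_am <- envelope_modulation(am, fs)
  spec <- Mod(stats::fft(e_am))^2
  freq <- (seq_along(spec) - 1) * fs / length(spec)
  peak_hz <- freq[freq > 10 & freq < fs / 2][which.max(spec[freq > 10 & freq < fs / 2])]
  expect_gt(peak_hz, 70)
  expect_lt(peak_hz, 120)

  flat <- sin(2 * pi * 300 * t)
  e_flat <- envelope_modulation(flat, fs)
  expect_lt(stats::sd(e_flat), 0.1 * stats::sd(e_am))

  expect_error(envelope_modulation(am, fs, spec = list(centers_hz = numeric(),
                                                       q = 4, compression = 0.3)),
               "empty filterbank")
  expect_error(envelope_modulation(am, fs,
                                   spec = list(centers_hz = c(100, 300),
                                               q = 4, compression = 0.3)),
               "above the f0 band")
})

test_that("feature correlation reproduces the direct Pearson formula", {
  x <- c(1.2, -0.5, 3.1, 0.4, 2.2)
  y <- c(0.3, 1.8, -0.9, 2.4, 1.1)
  got <- feature_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    ((length(x) - 1) * stats::sd(x) * stats::sd(y))
  expect_equal(got$r, r_hand, tolerance = 1e-12)

  expect_equal(feature_correlation(x, x)$r, 1, tolerance = 1e-12)

  t <- seq(0, 4 - 1e-9, by = 1e-3)          # whole periods
  expect_lt(abs(feature_correlation(sin(2 * pi * t), cos(2 * pi * t))$r), 1e-6)

  expect_warning(out <- feature_correlation(rep(1, 5), x), "constant")
  expect_true(is.na(out$r))
  expect_error(feature_correlation(x, y[1:3]), "length")
})

test_that("extracted features are zero-mean, band-confined, and co-sampled", {
  st <- synth_study_20s()
  ft <- st$features
  expect_equal(length(ft$fundamental), length(ft$envelope))
  expect_lt(abs(mean(ft$fundamental)), 1e-6 * stats::sd(ft$fundamental))
  expect_lt(abs(mean(ft$envelope)), 1e-6 * stats::sd(ft$envelope))
  band_fraction <- function(x, fs) {
    p <- Mod(stats::fft(x))^2
    freq <- (seq_along(p) - 1) * fs / length(p)
    freq <- pmin(freq, fs - freq)
    sum(p[freq >= 60 & freq <= 130]) / sum(p)
  }
  expect_gt(band_fraction(ft$fundamental, ft$fs), 0.9)
  expect_gt(band_fraction(ft$envelope, ft$fs), 0.9)
  # reference scale
  expect_equal(stats::sd(ft$fundamental), 0.02, tolerance = 0.1)
})
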