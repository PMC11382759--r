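test_that("f0 trajectories stay in range, honor the seed, and degenerate cleanly", {
  tr <- gen_f0_trajectory(10, c(70, 120), 0.5, seed = 4, fs = 2000)
  expect_true(all(tr$f0_hz >= 70 & tr$f0_hz <= 120))
  expect_equal(length(tr$f0_hz), 20000L)

  tr2 <- gen_f0_trajectory(10, c(70, 120), 0.5, seed = 4, fs = 2000)
  expect_identical(tr$f0_hz, tr2$f0_hz)
  tr3 <- gen_f0_trajectory(10, c(70, 120), 0.5, seed = 5, fs = 2000)
  expect_false(identical(tr$f0_hz, tr3$f0_hz))

  flat <- gen_f0_trajectory(1, c(70, 120), 0, fs = 2000)
  expect_true(all(flat$f0_hz == 95))

  expect_error(gen_f0_trajectory(-1, c(70, 120)), "duration_s")
  expect_error(gen_f0_trajectory(1, c(120, 70)), "increasing")
  expect_error(gen_f0_trajectory(1, c(70, 1200), fs = 2000), "Nyquist")
})

test_that("generated voices have the requested harmonic structure", {
  fs <- 4000
  peak_near <- function(x, target_hz, half_width_hz = 15) {
    p <- Mod(stats::fft(x))^2
    freq <- (seq_along(p) - 1) * fs / length(p)
    win <- freq >= target_hz - half_width_hz & freq <= target_hz + half_width_hz
    list(freq = freq[win][which.max(p[win])],
         power = max(p[win]), total = sum(p[freq > 5 & freq < fs / 2]))
  }
  flat100 <- gen_f0_trajectory(4, c(70, 120), 0, fs = fs)
  flat100$f0_hz[] <- 100
  pure <- gen_voice(flat100, 1, seed = 1, syllable_rate_hz = 0)
  pk1 <- peak_near(pure, 100)
  expect_equal(pk1$freq, 100, tolerance = 0.01)
  expect_gt(pk1$power / pk1$total, 0.4)    # essentially a pure tone

  flat90 <- flat100
  flat90$f0_hz[] <- 90
  five <- gen_voice(flat90, 5, seed = 1, syllable_rate_hz = 0, mod_depth = 0)
  for (k in 1:5) {
    pk <- peak_near(five, 90 * k)
    expect_equal(pk$freq, 90 * k, tolerance = 0.03)
    expect_gt(pk$power / pk$total, 0.005)  # harmonic clearly present
  }

  # harmonics beyond Nyquist are dropped with a warning
  expect_warning(gen_voice(flat100, 50, seed = 1), "Nyquist")

  # the f0 tracker recovers the generating trajectory (oracle round trip)
  st <- synth_study_20s()
  truth <- true_f0_at(st$f0, length(st$features$f0$f0_hz), st$features$fs)
  err <- abs(st$features$f0$f0_hz - truth)[st$features$f0$voiced]
  expect_lt(max(err), 2)
})

test_that("band-passed voices keep their f0-band power", {
  st <- synth_study_20s()
  fs <- 8000
  p <- Mod(stats::fft(st$voice))^2
  freq <- (seq_along(p) - 1) * fs / length(p)
  freq <- pmin(freq, fs - freq)
  in_band_before <- sum(p[freq >= 70 & freq <= 120]) / length(p)  # Parseval
  banded <- fundamental_waveform(st$voice, fs, 70, 120)
  expect_gt(sum(banded^2) / in_band_before, 0.5)
})

test_that("neural responses follow the generative forward model exactly", {
  fs <- 1000
  set.seed(41)
  n <- 3000
  f <- rnorm(n)
  feats <- stimulus_features(f, rnorm(n), NULL, fs)
  axis <- lag_axis()
  delta <- as.numeric(axis$lags_ms == 35)

  truth <- ground_truth(axis, kernel_alpha = delta,
                        kernel_beta = numeric(axis$n_lags),
                        attention_gain = 1.5, noise_sd = 0,
                        band_limit_hz = NULL)
  att <- gen_neural_response(feats, truth, attended = TRUE)
  # delta kernel at 35 ms: output is gain x f delayed by 35 samples
  expect_equal(att$samples[1, 36:n], 1.5 * f[1:(n - 35)], tolerance = 1e-12)

  ign <- gen_neural_response(feats, truth, attended = FALSE)
  expect_equal(att$samples[1, ], 1.5 * ign$samples[1, ], tolerance = 1e-12)

  # channels differ only in noise draws
  truth_n <- ground_truth(axis, noise_sd = 0.1, seed = 2)
  multi <- gen_neural_response(feats, truth_n, n_channels = 3)
  expect_equal(nrow(multi$samples), 3L)
  expect_false(identical(multi$samples[1, ], multi$samples[2, ]))
  expect_identical(gen_neural_response(feats, truth_n, n_channels = 3)$samples,
                   multi$samples)

  short <- stimulus_features(f[1:100], f[1:100], NULL, fs)
  expect_error(gen_neural_response(short, truth), "shorter than the kernel")
  expect_error(ground_truth(axis, attention_gain = 0.5), "attention_gain")
})

test_that("generate -> estimate round trip recovers the planted latency", {
  st <- synth_study_20s()
  axis <- lag_axis()
  truth <- ground_truth(axis, peak_latency_ms = 35, snr_db = 5, seed = 6)
  rec <- ffr_bandpass(gen_neural_response(st$features, truth))
  m <- fit_ridge(build_design(st$features, axis), rec, lambda = 1)
  env <- trf_envelope(trf_magnitude(m), fs = 1000)
  expect_lte(abs(axis$lags_ms[which.max(env[, "f"])] - 35), 2)
  expect_lte(abs(axis$lags_ms[which.max(env[, "e"])] - 35), 2)
})

test_that("synthetic cohorts satisfy their intended group criteria", {
  co <- gen_cohort(18, 25, 9, seed = 2)
  expect_equal(nrow(co), 52L)
  expect_equal(as.vector(table(co$group)[c("musician", "non-musician", "neutral")]),
               c(18L, 25L, 9L))
  # classification round trip at several seeds
  for (s in 1:3) {
    coh <- gen_cohort(6, 7, 5, seed = s)
    expect_identical(classify_participant(coh), coh$group)
  }
  expect_identical(gen_cohort(5, 5, 2, seed = 9), gen_cohort(5, 5, 2, seed = 9))
  expect_equal(nrow(gen_cohort(0, 0, 0)), 0L)
  expect_error(gen_cohort(-1, 0, 0), ">= 0")

  # chance-level answering of 30 four-option questions
  chance <- gen_cohort(40, 40, 20, seed = 3, p_correct = 0.25)
  expect_equal(mean(chance$percent_correct), 25, tolerance = 0.15)
})

test_that("WAV files round-trip through the writer and reader", {
  st <- synth_study_20s()
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(st$voice[1:16000], path, 8000)
  back <- read_wav(path)
  expect_equal(back$fs, 8000)
  expect_equal(back$samples, st$voice[1:16000], tolerance = 1e-3)
})
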