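# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# 20 s synthetic voice + extracted features (working rate 1000 Hz)
synth_study_20s <- function() cached("study20", {
  f0 <- gen_f0_trajectory(20, c(70, 120), 0.5, seed = 11, fs = 8000)
  voice <- gen_voice(f0, 5, seed = 12)
  list(f0 = f0, voice = voice,
       features = extract_stimulus_features(voice, 8000, out_rate = 1000))
})

# 60 s synthetic voice + features: the study-scale stimulus
synth_study_60s <- function() cached("study60", {
  f0 <- gen_f0_trajectory(60, c(70, 120), 0.5, seed = 1, fs = 8000)
  voice <- gen_voice(f0, 5, seed = 2)
  list(f0 = f0, voice = voice,
       features = extract_stimulus_features(voice, 8000, out_rate = 1000))
})

make_tone <- function(freq_hz, fs, duration_s) {
  sin(2 * pi * freq_hz * seq(0, duration_s, by = 1 / fs))
}

# true f0 of a generated trajectory, resampled to the feature rate
true_f0_at <- function(f0, n_out, out_rate) {
  stats::approx((seq_along(f0$f0_hz) - 1) / f0$fs, f0$f0_hz,
                xout = (seq_len(n_out) - 1) / out_rate, rule = 2)$y
}

# independent zero-phase low-pass for envelope oracles
oracle_lowpass <- function(x, cutoff_hz, fs, order = 5) {
  ba <- signal::butter(order, cutoff_hz / (fs / 2), "low")
  as.numeric(signal::filtfilt(ba$b, ba$a, x))
}
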