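# speechFFR

Temporal response functions for the cortical contribution to the speech
frequency-following response (speech-FFR).

## What this package is for

Neural populations track the fundamental frequency (f0) of a speaker's
voice. The cortical part of this frequency-following response appears at
latencies around 30–40 ms, grows when the speaker is attended rather
than ignored, and is a candidate marker for how experience — for
example, musical training — shapes early cortical speech processing.
`speechFFR` is for researchers who want to estimate this response from
continuous recordings (MEG/EEG sensor or source time series) and run the
accompanying statistics, and for methodologists who want a fully
synthetic, ground-truth-controlled test bed for the analysis chain.

The analysis models the neural response `y` as a lagged linear function
of two speech features,

    y_t = Σ_τ ( α_τ f_{t−τ} + β_τ e_{t−τ} ),     τ = −20 … 120 ms,

where `f_t` is the **fundamental waveform** (the stimulus band-passed
65–120 Hz) and `e_t` is the **envelope modulation** (the f0-rate
amplitude fluctuation of the higher harmonics, extracted through a
constant-Q filterbank with compressive envelopes). The coefficients
α_τ, β_τ — the temporal response functions (TRFs) — are estimated by
ridge regression (λ = 1). TRF magnitudes are summarized by their
Hilbert envelope; envelopes are tested per lag against TRFs fitted with
time-reversed features (10,000-permutation bootstrap, Bonferroni across
lags); and attentional modulation is scored per subject as
`Q = (a − i)/(a + i)` from the envelope values in the attended and
ignored conditions. Cohort statistics cover musician/non-musician
classification, musical-training scores, Shapiro–Wilk-gated t /
Mann–Whitney comparisons, Brown–Forsythe variance tests, Spearman
correlations with Benjamini–Hochberg adjustment, and Kruskal–Wallis
behavioural comparisons.

A synthetic-data module generates f0 trajectories, harmonic voices with
speech-like syllabic structure, neural responses convolved from known
Gabor kernels with a configurable attention gain and noise level, and
participant cohorts — so every stage is verifiable by parameter
recovery.

## Worked example

A complete synthetic study — 8 subjects, 30 s of stimulus, attended and
ignored conditions, attention gain 1.5, SNR 0 dB:

```r
library(speechFFR)

cfg <- pipeline_config(seed = 42, n_musicians = 3, n_nonmusicians = 4,
                       n_neutral = 1, duration_s = 30)
res <- run_pipeline(cfg, quiet = TRUE)

round(res$population_latency_ms, 1)
#> f_attended  f_ignored e_attended  e_ignored
#>       35.5       35.0       34.6       34.2

head(subset(res$qscores, feature == "f"), 4)
#>   subject feature         a         i         Q        group
#> 1     S01       f 0.5226328 0.3559912 0.1896619     musician
#> 3     S02       f 0.4077482 0.2705366 0.2022919     musician
#> 5     S03       f 0.7100549 0.4628714 0.2107408     musician
#> 7     S04       f 0.7641727 0.5211214 0.1891017 non-musician
```

The population peak latencies land at the planted kernel latency
(35 ms ± the per-subject jitter the generator drew). The per-subject
attention scores `Q` scatter around `(1.5 − 1)/(1.5 + 1) = 0.2`, the
value implied by the planted attention gain, and the attended-vs-ignored
envelope comparison is significant:

```r
res$stats$f$attention[c("test", "p")]
#> $test
#> [1] "t"
#> $p
#> [1] 0.001897...
```

The two stimulus features are nearly uncorrelated, as they should be if
they capture different aspects of the voice
(`res$stats$feature_correlation$r` here: 0.025).

Individual stages are ordinary functions: `extract_stimulus_features()`,
`notch()`, `resample_recording()`, `ffr_bandpass()`, `align_features()`,
`build_design()`, `fit_ridge()`, `trf_magnitude()`, `trf_envelope()`,
`noise_trf()`, `bootstrap_significance()`, `find_peak()`,
`attention_score()`, `classify_participant()`, `compute_scores()`,
`correlate_scores()`, `behavior_stats()`. See the methods vignette
(`vignettes/speechFFR-methods.Rmd`) for the model, the parameter
conventions, and the design decisions.

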