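---
title: "Modelling the cortical speech-FFR with temporal response functions"
author: "speechFFR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the cortical speech-FFR with temporal response functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechFFR)
```

## The scientific setting

When a listener hears running speech, neural populations track the
speaker's fundamental frequency (f0) and its harmonics.  This
frequency-following response (speech-FFR) has a cortical contribution
with a characteristic latency around 30--40 ms, and its strength depends
on whether the listener attends the speaker or ignores them in favour of
a competing voice.  `speechFFR` implements the analysis chain for
characterizing this response from continuous neural recordings: two
f0-band speech features are extracted from the stimulus audio, a linear
forward model maps their lagged copies onto the neural signal, the
resulting temporal response functions (TRFs) are tested against
time-reversed noise models, and attentional modulation and
musical-training effects are quantified at the cohort level.

Because real studies of this kind rest on many hours of MEG and
copyrighted audiobook stimuli, the package ships a first-class
synthetic-data generator: stimuli, neural responses with known
ground-truth kernels, and participant cohorts.  Every stage of the
pipeline is validated by recovering parameters the generator planted.

## The forward model

The neural response $y_t(v)$ at time $t$ in channel (or source point) $v$
is modelled as

$$ y_t(v) \;=\; \sum_{\tau=\tau_\min}^{\tau_\max}
   \bigl( \alpha_\tau(v)\, f_{t-\tau} \;+\; \beta_\tau(v)\, e_{t-\tau} \bigr), $$

where $f_t$ is the *fundamental waveform* (the stimulus band-passed
around the speaker's f0 range) and $e_t$ is the *envelope modulation*
(the f0-rate amplitude fluctuation of the higher harmonics).  The
coefficient sequences $\alpha_\tau$ and $\beta_\tau$ are the TRFs.  The
lag axis runs from $\tau_\min = -20$ ms to $\tau_\max = 120$ ms in 1 ms
steps (141 lags); negative lags are acausal and provide a built-in sanity
band.

`build_design()` materializes the lagged copies as a time $\times$
$2\cdot141$ matrix and `fit_ridge()` solves the penalized least-squares
problem $\min_w \lVert y - Xw\rVert^2 + \lambda\lVert w\rVert^2$ per
channel through one Cholesky factorization of $X^\top X + \lambda I$,
shared across channels, so that fitting a whole cohort against the same
stimulus costs little more than fitting one subject.  The penalty is
fixed at $\lambda = 1$ and applied to the raw (unstandardized) features;
no cross-validated search is performed.  Samples at the record edges,
where lagged features are zero-filled, are retained in the fit.

Because the features are confined to the f0 band, the fitted TRFs
oscillate near f0, and so do their absolute values.  `trf_magnitude()`
averages $\lvert\text{coefficient}\rvert$ over channels (for
three-component volumetric source points, the Euclidean norm across each
triplet is taken first), and `trf_envelope()` removes the oscillatory
carrier: the analytic-signal magnitude of the magnitude curve is low-pass
filtered at 70 Hz (zero-phase Butterworth, order 5, the lag axis treated
at the neural sample rate), and tiny negative values left by the filter
are clipped to zero.  Magnitudes are averaged across channels *before*
the envelope is computed; computing per-channel envelopes first and
averaging afterwards is a deliberate non-default, available by applying
`trf_envelope()` per channel.

### The feature scale convention

A fixed penalty is only meaningful at a fixed feature scale: ridge
shrinkage acts on directions of the design in proportion to
$d/(d+\lambda)$, where $d$ scales with $n \cdot \mathrm{var}(f)$.
`extract_stimulus_features()` therefore emits both features at a
documented reference RMS of 0.02 — the order of the f0-band RMS of
full-scale ($\pm 1$) speech audio, about $-20$ dB re full scale.  At this
scale $\lambda = 1$ sits in the flat, near-optimal part of the
recovery-versus-$\lambda$ curve for minute-scale records, and misaligned
(noise-model) fits, whose coefficient mass spreads into weakly excited
directions, are strongly shrunk.  The envelope modulation has no natural
units of its own (the auditory-periphery stages are compressive), so both
features share the same reference RMS, which also balances the two
blocks of the design.

## Feature extraction

**f0 tracking.** `extract_f0()` is a simplified YIN tracker: per frame
(default 40 ms, hop 10 ms) it evaluates the cumulative-mean-normalized
difference function, takes the first lag below an absolute threshold
(0.1) and descends to the local minimum, refines the lag by parabolic
interpolation, and flags frames whose best value exceeds 0.35 as
unvoiced.  Frame estimates are median-smoothed and interpolated to
per-sample resolution.  All frame computations are vectorized through FFT
cross-correlation, so minute-long audio tracks in seconds.  The tracker
is a commodity stage: `extract_stimulus_features(f0 = ...)` accepts an
externally supplied track (e.g. from a probabilistic tracker) in its
place.

**Fundamental waveform.** The stimulus is band-passed 65--120 Hz with a
fourth-order Butterworth filter applied forward--backward (zero phase).
Narrow band-passes at audio rates are numerically fragile in
transfer-function form, so all band-passes are designed analytically and
realized as cascaded second-order sections (analog prototype, band
transform pole by pole, bilinear transform biquad by biquad); the
realization is verified against an independent design in the tests.

**Envelope modulation.** The stimulus passes a constant-Q filterbank
(third-octave-spaced centres from 150 Hz to $\min(4\,\text{kHz},
0.45\,f_s)$, Q = 4, second-order band-passes).  Each band's envelope is
the analytic-signal magnitude, compressed by a power law with exponent
0.3; bands are summed with equal weight and the sum is band-passed
70--120 Hz (fourth order, zero phase).  The parameters mimic the
qualitative behaviour of auditory-periphery models (cochlear tonotopy,
compressive transduction, envelope coding); the across-scale derivative
stage of such models is omitted, as its numerical form is not pinned
down — a documented simplification, not a claim of equivalence.

The two features capture essentially unrelated aspects of the stimulus:
on the minute-long synthetic voices the Pearson correlation between
$f_t$ and $e_t$ is near zero, and `feature_correlation()` reports it.

Both features are demeaned, rescaled to the reference RMS, and
Fourier-resampled to the neural working rate (1000 Hz).  The final
band-passes are applied at the native audio rate; since all operations
involved are linear and the band lies far below either Nyquist
frequency, the order of filtering and resampling is immaterial.

## Conditioning of neural recordings

`neural_recording` objects carry a channels $\times$ time matrix, the
sample rate, an alignment offset, channel roles, a provenance log, and an
`edge_contaminated_ms` marker.  The conditioning chain follows the
acquisition order of FFR studies:

1. `notch()` — power-line removal at 50 Hz with a windowed-sinc
   (firwin-style) linear-phase FIR band-stop, transition bandwidth
   0.5 Hz, applied with group-delay compensation (net zero phase).
2. `resample_recording()` — down-sampling (e.g. 1017.25 Hz to 1000 Hz)
   by Fourier-domain resampling: the spectrum is truncated at the new
   Nyquist frequency, which is exact for band-limited signals and
   anti-aliased by construction.  A polyphase implementation of the
   awkward 4000/4069 ratio would need an impractically long filter; the
   spectral method is what mainstream M/EEG software uses.
3. `ffr_bandpass()` — 70--120 Hz second-order Butterworth, zero phase,
   selecting the band of the lower-pitched speaker's fundamental.
4. `align_features()` — the stimulus reaches the ear through ~2 m of
   tubing, a constant 6 ms acoustic delay; the features are delayed
   accordingly and both series trimmed to common support.

Zero-phase filtering uses odd-reflection padding; each operation raises
`edge_contaminated_ms` to 100 ms so downstream analyses can discount the
record edges.  All operations are per-channel and channel-order
preserving, and append to the provenance log.

The 65 Hz lower edge of the fundamental waveform versus the 70 Hz lower
edge of the envelope modulation and the neural band-pass is kept as an
intentional asymmetry of the analysis convention; both defaults are
exposed as arguments.

## The synthetic study

`gen_f0_trajectory()` draws a smooth f0 track: low-pass-filtered Gaussian
noise (default cut-off 0.5 Hz, a slow prosodic drift) squashed into the
target range (default 70--120 Hz, a low-pitched male voice) by a tanh
map.  `gen_voice()` synthesizes a harmonic complex following the track:
harmonic amplitudes decay as $1/k$; harmonics above the fundamental carry
an amplitude modulation at the f0 rate (depth 0.5), giving the envelope
modulation feature something real to detect; and a syllable-rate
(4 Hz) energy envelope modulates the whole voice, the canonical slow
amplitude structure of speech.

Two decoherence mechanisms emulate vocal-tract variability, with
deliberately different timescales.  The carrier phase of each harmonic
above the fundamental drifts with SD $\pi/2$ at about 1 Hz: this
decorrelates harmonic beat envelopes from the glottal cycle while
perturbing the composite waveform's instantaneous periodicity by well
under 2 Hz, keeping the voice trackable.  The amplitude-modulation phase
drifts with SD $\pi$ at about 3 Hz (phoneme-like rate): this decorrelates
the f0-rate envelope from the fundamental waveform and carries no pitch
information at all.  Without these mechanisms the two features of a
locked harmonic complex correlate strongly; with them, minute-long
records show the near-zero feature correlation characteristic of real
speech.

`ground_truth` bundles generating kernels with an attention gain
($\ge 1$), a noise level (absolute SD or SNR in dB), and a noise spectral
exponent (white by default; 1/f available).  The default kernels are
Gabor wavelets — a Gaussian envelope at the peak latency (default 35 ms,
width 6 ms) carrying a 95 Hz oscillation — band-limited to 70--120 Hz:
since both the features and the neural band are confined to the f0 band,
kernel components outside it are invisible to any analysis, and a
band-limited kernel is the physically meaningful truth for recovery
tests.  When an SNR is given, the noise SD is set relative to the
unit-gain (ignored-condition) clean signal, so both attention conditions
see the same absolute noise, as a sensor would deliver.

`gen_neural_response()` is the generative reading of the forward model:
the features are pushed through the same lagged design used for
estimation and multiplied by the stacked kernels, scaled by the attention
gain when attended, with independent noise per channel.  Generation and
estimation are therefore mutually consistent by construction: with zero
noise and vanishing penalty, `fit_ridge()` returns the generating kernels
to numerical precision.

`gen_cohort()` draws musical-training profiles that satisfy the
musician criteria (starting age $\le 7$, total training $\ge 10$ years,
currently training) for the musician group, the stricter non-musician
criteria (never played, or started $\ge 7$ with $\le 3$ years and not
currently training) for the non-musician group — with 60% of
non-musicians never having played — and violate exactly one musician
criterion for the neutral group.  Behavioural scores come from binomial
answering of 30 four-option comprehension questions (chance level 25%).
Per-subject TRF variability is exposed as two free parameters — a
log-normal amplitude scale (SD 0.2) and a latency shift (SD 1 ms) —
because the statistical structure of inter-subject TRF variability is
not an established quantity; both default to modest values and are
settable.

**What the generator does not emulate:** formants and prosody beyond f0,
room acoustics, the simultaneous competing-voice mixture (attention
enters only as a gain on the response), MEG sensor physics, head
geometry, and source reconstruction.  Passing recovery tests therefore
demonstrate that the analysis chain is correct and well-calibrated for
band-limited responses generated by the assumed linear model — not that
the model captures everything in real cortical data.

## Noise models and significance

Following standard practice for continuous-speech forward models, null
TRFs are obtained by reversing the feature streams in time and rerunning
the full TRF-plus-envelope pipeline against the untouched response
(`noise_trf()`).  One reversal yields one noise model; further models add
a seeded random circular shift to the reversed streams (a standard
surrogate construction), with 10 models per subject by default.

`bootstrap_significance()` resamples the noise-model envelopes with
replacement (default 10,000 draws) to build a per-lag null distribution,
computes the empirical p-value $p = (1 + \#\{\text{null} \ge
\text{observed}\})/(n_\text{perm}+1)$ — the $+1$ correction keeps p-values
strictly positive — and applies the Bonferroni correction across the 141
lags, masking at $\alpha = 0.05$.  Two numerical consequences are worth
knowing.  First, rejectability requires $n_\text{perm} \ge m/\alpha - 1
\approx 2820$; at the default 10,000 permutations the smallest corrected
p-value is about 0.014.  Second, with $k$ noise models the null has
effective granularity $1/(k+1)$ per lag, so the corrected test is
conservative for small $k$; the type-I calibration test in the suite
confirms the family-wise error stays at or below $\alpha$ under the
global null.

A caveat found while validating the generator, and worth stating
honestly: in the *noise-free* regime, the time-reversed null of a
continuously voiced narrowband stimulus is not a clean floor.  The
forward and reversed f0 trajectories repeatedly cross in frequency, and
every crossing contributes a coherent chunk to the reversed fit, so the
noise-TRF envelope peak does not vanish with record length.  In the
regime the method is actually used in — long, noise-dominated recordings
— the null is exchangeable with the genuine fit and the procedure is
calibrated, which is what the test suite verifies; at the genuine peak's
latency the noise envelopes sit far below the genuine envelope even at
desk scale.

## Peaks, attention, and cohort statistics

`find_peak()` takes the global maximum of the envelope over the lags the
significance mask allows, breaking ties toward the earliest lag; with no
significant lag the peak is flagged absent rather than fabricated.
Population peak latencies are the mean of included subjects' latencies
per condition and feature, after excluding participants without
significant peaks and outliers outside the $Q1 - 1.5\,\mathrm{IQR}$ /
$Q3 + 1.5\,\mathrm{IQR}$ fences (`iqr_exclude()`); all participants then
rejoin for the analysis of envelope values at the population latency.

Attentional modulation is quantified per subject as
$Q = (a - i)/(a + i)$, the normalized difference of the envelope values
in the attended and ignored conditions (`attention_score()`); $Q$ is
undefined (reported missing) when $a + i = 0$.  For a pure gain $g$ on
the response, $Q$ recovers $(g-1)/(g+1)$.

Location comparisons (`compare_conditions()`) gate on Shapiro--Wilk
normality of both samples at $\alpha = 0.05$ — the gate level is not a
universal constant and is exposed as an argument — and use an unpaired
pooled-variance Student's t-test when both pass, otherwise a
Mann--Whitney-U test.  Variance comparisons use the Brown--Forsythe test
(`compare_variances()`), realized as a one-way ANOVA on absolute
deviations from group medians.  Musical-training scores
(`compute_scores()`) normalize starting age (inverted, so an earlier
start scores higher — a documented, configurable direction), total
training years, current weekly hours, and lifetime instrument count by
their cohort maxima; participants who never played contribute no age
component.  Correlations of neural magnitudes with the four scores and
their aggregate use Spearman's rank correlation with Benjamini--Hochberg
adjustment across the five tests (`correlate_scores()`); behavioural
analyses use Spearman correlations and a Kruskal--Wallis comparison of
the three groups (`behavior_stats()`).

## The pipeline and reproducibility

`run_pipeline(pipeline_config(...))` executes the whole synthetic study:
stimulus, features, cohort, per-subject attended/ignored responses,
conditioning, one shared ridge factorization for all subjects and
conditions, noise models, bootstrap significance, peaks, population
latencies, attention scores, and the full battery of cohort statistics.
A single master seed fans out to per-stage seeds
(`seed * 100 + offset`), so any stage can be rerun in isolation and
identical configurations give byte-identical outputs.  With an
`output_dir`, all tables are persisted as CSV alongside the verbatim
config and a JSON report with provenance.

The study scales used by the test suite and the acceptance script are
chosen to exercise the method at full fidelity while remaining desk
friendly: 60 s stimuli for recovery and feature checks, 8 subjects for
the end-to-end study, 20 subjects for attention-score recovery, and 200
pure-noise repeats at 1,000 permutations for calibration.  Kernel
recovery is assessed at SNR 0 dB; attention-score recovery at SNR 10 dB,
since the score is a ratio of envelope values whose common noise floor
biases it toward zero at high noise.

## Known limitations

* The auditory-periphery stage is a parameterized sketch (constant-Q
  bands, power-law compression, analytic envelopes), not a validated
  cochlear model; absolute envelope-modulation values are convention,
  which is why the reference-RMS scale exists.
* The significance machinery inherits the granularity of the
  noise-model count; with the default 10 models the per-lag null is
  coarse and the Bonferroni test conservative.
* The generator's attention effect is a pure gain; latency or shape
  changes under attention are not simulated, so tests cannot speak to
  them.
* Sensor-noise weighting, artifact rejection, and source reconstruction
  are out of scope; the pipeline consumes sensor- or source-level time
  series as given.
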