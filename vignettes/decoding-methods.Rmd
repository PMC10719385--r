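---
title: "Decoding finger movements from MMG and EMG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding finger movements from MMG and EMG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mmgdecode)
```

## The problem

Magnetomyography (MMG) with optically pumped magnetometers records the
magnetic counterpart of muscle electrical activity without skin contact.
This package implements a complete pipeline for asking how well individual
finger movements — index (DII) and little finger (DV) flexions, plus a
no-movement state — can be decoded from short windows of simultaneous MMG
and surface EMG recordings of the forearm flexors, and for comparing the
two modalities: classification accuracy under trial-stratified
cross-validation, channel-level attribution of what the classifier uses,
between-modality agreement, and significance against an empirical chance
level.

Because the kind of paired recording this addresses is not publicly
deposited, the pipeline is driven by a synthetic generator whose study
conditions mirror the emulated protocol; every stage accepts real data in
the same containers.

## Synthetic study conditions

`generator_config()` fixes the emulated acquisition: three sessions
(all-DII, all-DV, alternating) of 30 cued trials, 5 s per trial, movement
duration 1 s, sampling rate 2343.8 Hz, 4 bipolar EMG channels and 4
biaxial magnetometers (8 MMG channels, axes Y along the forearm and Z
perpendicular to the skin). Choices the protocol leaves open were fixed
once, as follows:

* **Cue-to-onset latency** (`cue_offset`, default 0.3 s): reaction times
  for cued single-finger flexions are a few hundred milliseconds; onsets
  are treated as given, as if read from a movement sensor.
* **Background model**: per channel, 1/f Gaussian noise (unit RMS,
  synthesized in the frequency domain), white sensor noise (0.3 RMS), and
  a 50 Hz line component of amplitude 1 with random phase. Units are
  arbitrary; only ratios matter downstream because every feature is
  z-scored.
* **Movement burst**: band-limited (25–100 Hz) Gaussian noise under a
  tapered-cosine (Tukey, taper 0.3) envelope spanning the 1 s movement.
  The taper keeps the on/offset smooth (the "consistent speed"
  instruction) while the burst is at full strength during the 0–300 ms
  post-onset interval that the window sampler draws from. A raised cosine
  over the full second was tried first and rejected: it puts only the weak
  early ramp inside the sampled windows, which contradicts the design
  premise that this interval samples the movement at full strength, and it
  caps decoding accuracy far below the regime the pipeline is meant to
  emulate.
* **Spatial gains** (`default_gain_matrix()`): ulnar-side channels
  (EMG-2/4, OPM sensors 2/4) respond preferentially to DV, radial-side to
  DII (1.0 vs 0.35), and the skin-perpendicular Z axis is weighted above Y
  (1.0 vs 0.6). These serve as ground truth for attribution-recovery
  tests.
* **SNR** (`snr_emg = 1.0`, `snr_mmg = 0.6`): burst RMS relative to the
  channel's background RMS inside 25–100 Hz, at unit gain. The pair was
  calibrated once so that the full protocol lands in the observed
  performance regime for this kind of recording (EMG ≈ 0.95, MMG ≈ 0.86
  mean accuracy) with EMG clearly above MMG, and then frozen.

What the generator does **not** model: volume conduction or magnetic
forward fields (channels are conditionally independent given the class),
motor-unit discharge structure, movement artefacts, heartbeat
contamination, or sensor drift. Passing tests on these data therefore
demonstrate that the pipeline recovers the statistical structure it
assumes — class-dependent spatial gain patterns in band-limited envelopes —
not that it handles every pathology of real recordings.

## Preprocessing

`preprocess_recording()` applies, in order: per-channel demeaning over the
whole session (the scope of demeaning is unspecified in the emulated
protocol; per-session is the simplest choice consistent with a single
continuous recording), a 25–100 Hz zero-phase fourth-order Butterworth
band-pass, a 49–51 Hz zero-phase fourth-order band-stop, the magnitude of
the Hilbert analytic signal, and resampling at 200 Hz.

Numerical choices:

* **Zero phase**: each IIR filter is applied forward and backward.
  The signal is extended by odd reflection (≥ 2048 samples per side) so
  transients decay inside the padding, and the result is the average of
  the forward–backward and backward–forward passes. The average has the
  same squared magnitude response and makes the operation exactly
  symmetric under time reversal, which is asserted at 1e-8 relative
  tolerance in the tests. "Fourth order" is the design order of the
  one-way filter; the double pass squares its magnitude response.
* **Analytic signal**: FFT-based, zero-padded to a 5-smooth length. A 5 s
  trial at 2343.8 Hz is 11719 samples — a prime — so session lengths have
  large prime factors for which mixed-radix FFTs degenerate; padding keeps
  them fast, and the padding artefacts are confined to the session edges,
  which the window sampler excludes (0.5 s guard).
* **Resampling** to 200 Hz: the rate ratio 1000/11719 is irreducible, so
  neither a practical polyphase implementation nor an exact FFT-length
  resample exists. The implementation uses a zero-phase windowed-sinc
  anti-alias filter (513-tap Hamming FIR, cutoff at 90 % of the output
  Nyquist) followed by linear interpolation on the output grid; at a 12×
  oversampled, low-passed input the interpolation error is far below the
  band-limited fidelity targets asserted in the tests (< 1 % RMS for
  tones, < 3 % for envelopes band-limited under 50 Hz). Small negative
  undershoots of the interpolated envelope are clipped at zero.

## Window sampling and leakage control

Windows are 100 ms (20 samples at 200 Hz). Movement windows are drawn
0–300 ms after onset from events of their class; no-movement windows are
drawn −1500–0 ms relative to every onset. Splits are made over **trials**,
never windows, so within-trial autocorrelation cannot leak across splits:
a stratified k-fold plan assigns each trial to exactly one test fold, and
in each fold 500 windows per class are sampled (uniformly, with
replacement over admissible trial/offset pairs) from the fold's training
trials and 100 per class from its test trials — the nested per-fold
version of the 500/100 sampling scheme.

One subtlety: with a 0.3 s cue-to-onset latency, the −1500–0 ms interval
crosses the 5 s trial boundary. A window is owned by the physical trial
that contains it and must lie entirely inside that trial; fold membership
is checked against the owner. Pre-onset windows therefore mostly come from
the late rest period of the preceding trial, and no-movement draws are
stratified equally over owner trials of the two movement classes. Windows
in the first and last 0.5 s of a session are excluded (filter and FFT edge
effects live there).

Each `(time, channel)` feature is z-scored with mean and standard
deviation computed over the window dimension of the **training** split
only, then applied unchanged to the test split; a constant feature raises
an error naming the feature. Tests assert that a shifted test set does not
come out centred — i.e. that moments are never refitted.

## The classifier

Input windows are `T × C` matrices (20 × 4 EMG or 20 × 8 MMG), convolved
along time with channels as feature maps:

1. **Residual block**: pointwise convolution (kernel 1, 128 filters, no
   bias) → batch norm → GELU → zero-padded kernel-3 convolution back to
   `C` filters (no bias) → batch norm → GELU → add the block input → GELU.
2. **Head**: zero-padded kernel-3 convolution, 16 filters, stride 2, with
   bias → GELU → flatten (160 features for T = 20) → dropout 0.1 →
   FC(100) → GELU → dropout → FC(100) → GELU → dropout → FC(3) → softmax.

GELU is the exact `x·Φ(x)`. Training minimizes mean categorical
cross-entropy with Adam (learning rate 0.01, β₁ = 0.9, β₂ = 0.999), batch
size 250, shuffling every epoch, 250 epochs by default with no early
stopping, schedule, or validation split. Open details were fixed as
follows: batch norm normalizes each filter over batch × time with biased
batch variance, running moments with momentum 0.99 for inference;
"kernel 3×3" is read as kernel length 3 for a 1-D convolution; "same"
padding with ceil-division output lengths (stride 2 maps 20 → 10);
weights use fan-in-scaled Gaussian initialization (`sd = sqrt(2/fan_in)`)
from the run seed; dropout sits after the flatten and the two hidden FC
layers only.

The numerical core (forward, backward, Adam) is compiled (RcppArmadillo)
and runs in single precision — the conventional precision for this model
family. Inside the compiled path the normal CDF of the GELU is evaluated
with a rational erf approximation on top of a polynomial exponential
(absolute error ~1.5e-7, below the single-precision noise floor), and the
shared `exp(-x²/2)` is cached so the backward derivative needs no further
transcendental calls; the exported `gelu()` and the pure-R reference
backend use the exact `pnorm` form. The reference double-precision
implementation of the full forward/backward lives in the package and the
two backends are cross-checked to ~1e-6 relative in the tests, alongside
finite-difference gradient checks.
Training is deterministic given the seed within a backend; the two
backends use different RNG streams for shuffling/dropout and are not
bit-identical to each other.

Model evaluation is stratified five-fold cross-validation at the trial
level, one model trained from scratch per fold. When both modalities are
evaluated, the same fold plan and the same window positions are used for
both, so the EMG and MMG test predictions are aligned window-for-window —
this alignment is what the agreement and McNemar analyses require.

## Attribution

`integrated_gradients()` attributes the per-sample cross-entropy loss at
the true label (deliberately the loss, not the predicted-class logit) to
input features: with an all-zeros baseline and m = 6 interpolation levels
linearly spaced on [0, 1] including both endpoints, the attribution is
`(x − x₀) ×` the plain average of the loss gradients at the interpolated
inputs. `channel_importance()` L1-normalizes each sample's attribution map
(the normalization scheme is a package choice; the alternative of no
normalization is available), averages over time, then over test samples,
per fold. Signed averages are the headline score; mean absolute
attributions are reported alongside and used for rank-based ground-truth
recovery because signed attributions of opposing classes can cancel.

The Riemann approximation is validated two ways: completeness — the summed
attribution converges to `L(x) − L(x₀)`, asserted within 1e-3 at m = 2000
on a smooth toy network — and the coarse m = 6 sum agreeing with the
m = 2000 oracle within 10 %. An exact linearity identity is not available
for this architecture (the softmax cross-entropy loss is never linear in
the input), so convergence and symmetry properties (duplicated channels
score equally; an ignored channel scores zero) stand in for it.

## Statistics

* **Empirical chance level**: training labels are permuted and the full
  cross-validated accuracy recomputed `n_perm` times; the p-value is the
  fraction of null values exceeding the observation, reported as
  `< 1/n_perm` when none does (a `(r+1)/(n+1)` estimator is available
  behind a flag). Cohen's d is the observation minus the null mean over
  the null's sample standard deviation. The full 1000-permutation protocol
  is configurable but far beyond a desk-scale run; scripts and tests use
  reduced permutation pipelines (two folds, 100/50 windows per class,
  10–15 epochs), which leaves the null's location at chance level — what
  the p-value and d statistics actually consume.
* **5×2-CV F-test**: five replications of stratified twofold
  cross-validation over trials; both models are trained and tested on
  identical splits; `f = Σd²ᵢⱼ / (2Σs²ᵢ)` is referenced to F(10, 5). If
  every replication variance is zero the statistic is undefined and an
  error is raised.
* **McNemar**: discordant counts over aligned predictions with the
  continuity-corrected statistic `(|b−c|−1)²/(b+c)` against χ²(1) — the
  form standard in the classifier-comparison literature — with Cohen's
  `g = |b/(b+c) − ½|`.
* **Agreement**: percentage agreement and Cohen's kappa
  `(p_o − p_e)/(1 − p_e)`; kappa from raw vectors and from the consensus
  matrix are two code paths cross-checked in tests.

## Problem sizes and determinism

The analysis scripts and the acceptance script run the full protocol
(5 folds × 100 epochs per modality — accuracy plateaus well before that on
these conditions, consistent with the loss curves the package exports) and
reduced-scale permutation (30–100 permutations) and 5×2 (40-epoch)
stages; the methods themselves scale to the full 250-epoch,
1000-permutation protocol unchanged. Every stochastic stage draws its seed
deterministically from one master seed via a Lehmer-style mixer
(`derive_seed()`), so a report is reproducible from its provenance block
(config hash, seed, package version), and written artifacts carry MD5
checksums that `verify_report_files()` re-validates.

## Known limitations

* The generator's channels are conditionally independent given the class;
  real EMG/MMG channels share volume-conducted and common-mode components,
  so real between-channel correlation structure is absent.
* Single-precision training means results are reproducible bit-for-bit
  only within the compiled backend on a given platform.
* Serialization is plain TSV (data + channel table + metadata header), not
  a binary scientific container; it is self-describing but not
  space-efficient for long raw recordings.
* Confidence intervals for Cohen's d are not computed: the downstream
  consumers of this pipeline report them without a stated method, and
  guessing one was out of scope.
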