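---
title: "Methods: multi-modal physiological emotion recognition in emofuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal physiological emotion recognition in emofuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`emofuse` implements an end-to-end pipeline for binary arousal/valence
recognition from three peripheral physiological channels — electrocardiography
(ECG), electrodermal activity (EDA) and respiration (RSP) — rated per trial on
1–9 self-report scales and binarized at the scale midpoint. It has five parts:

1. a **synthetic trial generator** with exact ground truth (R-peak times, SCR
   event times, breath-cycle boundaries);
2. **preprocessing**: zero-phase FIR band-pass filtering and Hamilton-style
   QRS detection for ECG, sparse non-negative deconvolution for EDA,
   trough-to-trough cycle segmentation for RSP, and per-subject baseline
   compensation;
3. a **58-feature extractor**: 47 heart-rate-variability (HRV) features
   (14 time-domain, 4 frequency-domain, 29 non-linear), 4 EDA features and
   7 RSP features;
4. **classical baselines** (SVM, random forest, KNN) evaluated under a
   fully-balanced-subset protocol with random/majority reference classifiers
   and paired t-tests;
5. a **multi-input 1D convolutional network (MI-DCNN)** — one convolutional
   branch per modality ending in global average pooling (GAP), concatenated
   and classified by two fully connected layers — trained from scratch with
   Adam and cross-entropy, plus single-input variants for fusion comparisons.

# The synthetic-data generator

Real multi-channel affective datasets of this kind are rarely redistributable,
so the generator is a first-class, tested module: it defines the study
conditions under which every claim in this package is evaluated.

**ECG.** A template PQRST beat (five Gaussian deflections, R amplitude
1 mV) is placed at R-times drawn from a stochastic RR tachogram: Gaussian
AR(1) innovations with standard deviation equal to the SDNN target and lag-1
autocorrelation $\phi = 1 - \mathrm{RMSSD}^2 / (2\,\mathrm{SDNN}^2)$, which
makes the expected RMSSD of the series hit its target exactly when
$\mathrm{RMSSD} \le 2\,\mathrm{SDNN}$ ($\phi$ is clamped at $-0.99$ beyond
that; targets beyond $2\sqrt{2}\,\mathrm{SDNN}$ are rejected as infeasible).
A 0.25 Hz baseline-wander sinusoid (0.05 mV) and white noise are added. We
chose template superposition over a dynamical-system ECG model because the
R-times are then *exact* ground truth — the test surface for the QRS
detector.

**EDA.** Tonic level plus a very slow drift, with skin-conductance responses
(SCRs) generated as a Poisson event process (driver impulses, amplitude
jittered ±20%) convolved with a two-exponential Bateman kernel
($\tau_{\text{rise}} = 0.7$ s, $\tau_{\text{decay}} = 3$ s).

**RSP.** A quasi-sinusoid with per-cycle period and amplitude jitter and a
continuous phase, so trough boundaries are exact.

**Score → parameter mapping.** Linear in (score − 5), the simplest monotone
encoding of the premise that arousal activates the autonomic channels: per
unit of (arousal − 5) × `arousal_effect`, mean heart rate rises 3 bpm, SCR
rate 1 /min, breathing rate 0.8 breaths/min. Valence skews the RR innovations
(heart-rate asymmetry) and perturbs breathing regularity via
`valence_effect`. Per-subject additive Gaussian offsets (HR sd 3 bpm, tonic
sd 0.3 µS, SCR rate sd 0.8 /min, breath sd 1 /min) create between-subject
variability, and every subject gets a 60-s neutral baseline recording
(scores ≡ 5) to support baseline compensation.

**Defaults.** 52 subjects × 12 trials of 34–201 s (uniform), ECG 250 Hz,
EDA/RSP 25 Hz, noise SDs 0.05 mV / 0.01 µS / 0.05 a.u. The acquisition rates
are conventional for laboratory polygraphy; all are configurable.

What the generator does **not** emulate: real QRS morphology variation,
ectopic beats, motion artifacts, electrode drift, respiratory sinus
arrhythmia coupling between channels, and any nonlinear or saturating
score–physiology relationship. Passing tests therefore demonstrate that the
pipeline recovers the *kind* of structure it models, not performance on real
recordings.

# Preprocessing choices

- **Filtering**: windowed-sinc FIR band-pass (3–45 Hz for QRS detection),
  0.5 s of taps, applied forward–backward so the net phase is zero and
  R-peak latencies are preserved. Note the forward–backward pass squares the
  magnitude response; band edges are quoted for the single pass.
- **QRS detection**: differentiate → rectify → 80 ms moving-average envelope
  → adaptive threshold tracking running QRS/noise peak estimates → 200 ms
  refractory period → back-search of the filtered-ECG maximum (±100 ms). An
  empty result is a flagged empty series, never an error.
- **NN artifact rule**: intervals outside (250, 3000) ms or deviating more
  than 30% from the running median of the last 11 accepted intervals are
  removed. The rule is configurable; the thresholds are conventional.
- **EDA decomposition**: conductance ≈ tonic + kernel ⊛ driver with a
  non-negative sparse driver. The tonic is a smoothing spline through a
  running lower envelope; the driver solves an L1-regularized non-negative
  least-squares deconvolution by FISTA (120 iterations, Lipschitz constant
  from the kernel's peak spectral power). This is the same model class as
  the convex-optimization decompositions used in the EDA literature, reduced
  to a form whose solution we can test against simulator ground truth; the
  full quadratic program is out of scope. Driver mass is clustered into
  events (gaps > 0.5 s split clusters), thresholded at 0.01 µS. If the
  solver fails, a low-pass/high-pass split is used with a warning.
- **Breath segmentation**: detrend (20-s moving average) → 0.25-s smoothing
  → alternating extrema with minimum period 1 s and prominence ≥ 0.1 × SD →
  trough-to-trough cycles. Boundary samples count as troughs when the trace
  starts/ends low, so edge cycles are kept.
- **Baseline compensation**: per-feature subtraction (or division) of the
  subject's neutral-baseline feature vector; reduces between-subject
  variance caused by subject offsets.
- Event times are seconds from trial start; sample indices are 1-based (R
  convention).
- Analysis is whole-trial; windowed analysis can be had by segmenting trials
  upstream.

# The 58-feature registry

The registry fixes exactly 58 names (closed world): extraction always emits
all of them and nothing else; non-finite values are flagged, never dropped
silently.

**Time domain (14).** RMSSD, MeanNN, SDNN, SDSD, CVNN, CVSD, MedianNN,
MadNN (×1.4826), MCVNN, IQRNN, pNN50, pNN20, TINN, HTI. The NN histogram
uses the conventional 7.8125 ms (1/128 s) bins; TINN is the base width of
the least-squares triangular fit anchored at the modal bin; HTI is total
count / modal count.

**Frequency domain (4).** The tachogram is cubic-spline interpolated to
4 Hz and a Welch periodogram (Hann, 50% overlap) is integrated over
HF = [0.15, 0.4] Hz and VHF = [0.4, 0.5] Hz; HFn = HF / power in
[0.04, 0.5]; LnHF = ln HF. LF is deliberately omitted from the registry —
the feature set mirrors the short-recording convention in which LF is
unreliable. A flat tachogram yields HF = 0 and the finite sentinel
LnHF = −50.

**Non-linear (29).** Poincaré: SD1 = RMSSD/√2 (second moment of successive
differences about zero, so the identity SD1 = RMSSD/√2 is exact),
SD2 = √(2 SDNN² − SD1²), SD1SD2, ellipse area S = π·SD1·SD2, CSI = SD2/SD1,
CVI = log10(16·SD1·SD2), Modified CSI = (4 SD2)²/(4 SD1). Fragmentation
(inflection/segment statistics of the sign sequence of successive
differences): PIP, IALS, PSS (% in segments < 3), PAS (% in strict
alternation runs ≥ 4). Heart-rate asymmetry on the Poincaré plot with
deceleration = RR lengthening: Guzik index (distance shares), slope index
(phase-angle shares), area index (sector-area shares), Porta index (% of
off-diagonal points below the identity), and the short/long-term
partitions SD1d/SD1a, SD2d/SD2a (zero-difference mass split evenly),
C1d/C1a, C2d/C2a, Cd/Ca, SDNNd/SDNNa — each pair an exact decomposition
(C1d + C1a = 1, etc.). ApEn and SampEn use m = 2, r = 0.2 × SD of the
analyzed series, Chebyshev distance; SampEn counts self-excluded template
pairs over a common template set at both lengths. Degenerate zero-variance
series return documented sentinels (ratios 0, asymmetry percentages 50,
entropies 0).

**EDA (4)** SCR_count_per_min, SCR_mean_amplitude, tonic_mean, phasic_sd;
**RSP (7)** amplitude mean/max/variance plus breath_rate_mean,
cycle-duration mean/SD and amplitude CV. Only the counts (4 and 7) are
fixed by the upstream design; these identities are our documented choice
and are pinned by the registry so the 58-length contract holds.

# Balanced-subset evaluation protocol

Mid-scale binarization (score ≤ 5 → "low") leaves unbalanced classes, so
evaluation uses five *fully balanced subsets*: each keeps every
minority-class row plus an independent equal-size majority sample. Per
subset, stratified 5-fold cross-validation gives an 80/20 train/test
division per fold; standardization and hyperparameter grid search (inner
3-fold CV) are fit on the training split only — the leakage-free reading of
the protocol, which we chose deliberately where the original description is
ambiguous about the relation between the 80/20 split and the 5-fold CV. A
subset's score is its fold mean; the reported value is mean ± SD over
subsets. Grids: SVM (RBF) C ∈ {0.1, 1, 10} × γ ∈ {0.25, 1, 4}/p; RFC 200
trees, mtry ∈ {0.25, 0.5, 1}·√p; KNN k ∈ {3, 5, 7, 11}.

On any balanced binary test set the majority classifier scores exactly 50%
accuracy and macro F1 = 1/3 (one class has F1 = 2/3, the other 0) — the
analytic reference the protocol is checked against.

# The multi-input DCNN

Each branch stacks three convolution blocks; a block is
[conv → ReLU → batch norm] × 2 → max-pool(2), following the
activation-before-normalization order of the source architecture diagram.
The default parameterization (filters × kernel, per-layer strides):

| branch | block 1 | block 2 | block 3 | GAP |
|--------|---------|---------|---------|-----|
| 1 (ECG, 2560 samples) | 128×32, s(2,2) | 128×32, s(2,1) | 128×16, s(1,1) | 128 |
| 2 (EDA, 640) | 64×16, s(2,2) | 64×16, s(3,3) | 32×4, s(1,1) | 32 |
| 3 (RSP, 640) | 128×16, s(3,3) | 64×16, s(2,2) | 64×8, s(1,1) | 64 |

GAP reduces each branch to its filter count; concatenation gives
128 + 32 + 64 = 224 features, classified by a 64-unit ReLU layer and a
2-way softmax. The stride table is read column-wise per branch (the
three-column layout of the source table); both the stride assignment and
the two-conv-layers-per-block reading are configurable should a different
interpretation be preferred. Input lengths are not dictated by the
architecture; the defaults above satisfy every stride/pool schedule, and
`branch_config()` rejects inputs below the analytically derived minimum.

Inputs are whole trials linearly resampled to the branch input length and
standardized per channel with training-set statistics (a per-trial
standardization would erase the level differences that carry signal).
Training is mini-batch Adam (lr 1e-3, batch 32) on the cross-entropy, with
optional early stopping on the training loss (`patience`). All layers —
conv (im2col + BLAS), ReLU, batch norm, max-pool, GAP, dense, softmax —
are implemented in the package with exact analytic backward passes; the
test suite checks them against brute-force forward oracles and numerical
differentiation.

Single-input variants reuse the branch-1 trunk: one modality as a 1-channel
input, or all three resampled to a common length and stacked as 3 channels
of one input, whose first-layer kernels then span all channels (shared
filters) — the design contrast the multi-input model is compared against.

# Desk-scale study sizes

Simulation studies in the tests and the acceptance script use a reduced
preset chosen as a realistic desk-scale workload:

- separability condition: 20 subjects × 12 trials of 60 s, `arousal_effect
  = 3`, low noise; `midcnn_spec_desk()` (same topology, 16/8/8-filter
  blocks, inputs 512/128/128, 32 hidden units), ≤ 15 training epochs;
- directional comparisons: 10 seeds × (10 subjects × 10 trials of 34 s) at
  `arousal_effect = 1.5`, 8 epochs — a moderate regime where models are off
  ceiling and architecture differences are visible.

Expected behavior, verified by the test suite: above 90% test accuracy for
both the fusion SVM and the MI-DCNN under the separability condition;
chance-level accuracy (inside the 99% binomial CI of 0.5) under permuted
labels or a zero effect; MI-DCNN ≥ stacked single-input DCNN on average
over seeds; and fusion-SVM accuracy within 0.05 of the best single
modality on average. The last margin matters: with ~80-trial balanced
subsets, the 51 feature dimensions that a single strong modality does not
need act as noise for the fusion SVM, which can therefore sit slightly
below the best single modality — the feature-superset argument holds only
up to estimation noise.

# Numerical notes and limitations

- Max-pooling drops tail samples (floor semantics); same-padding output
  length is ceil(L/stride), matching common deep-learning conventions.
- Batch normalization uses biased batch variance, ε = 1e-5, running-statistic
  momentum 0.9; training mode requires batches ≥ 2 (mini-batches of 1 are
  skipped).
- The FISTA deconvolution is not the exact quadratic program of the convex
  EDA literature; amplitudes of closely spaced SCRs can merge (events closer
  than ~0.5 s are reported as one).
- Determinism: every stochastic step (simulation, subset sampling, fold
  assignment, initialization, shuffling) derives its seed from the caller's
  seed, so identical configurations reproduce results bit-for-bit.
- The entropy estimators are O(n²) and intended for NN series of a few
  hundred intervals, not raw waveforms.
- Whether the original feature table's "S" denotes the Poincaré ellipse area
  is not stated there; the ellipse area is assumed and documented.
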