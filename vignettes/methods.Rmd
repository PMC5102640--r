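---
title: "Methods: from raw fNIRS intensities to TBI classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw fNIRS intensities to TBI classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its science: the models and
conventions each stage implements, the tunable parameters and why their
defaults are what they are, what the synthetic cohort generator does and
does not emulate, and the design choices made where the design was
genuinely open. It states no empirical result that the test suite does
not itself compute.

## 1. The measurement model

A continuous-wave fNIRS instrument illuminates the forehead at two
wavelengths (730 and 850 nm) and records detected intensity on 16
source–detector channels at 2 Hz. Concentration changes of the two
hemoglobin chromophores are recovered in three steps, each a pure
function of its inputs and configuration (`optical_config()`):

* **Normalization and optical density.** Each channel/wavelength trace is
  divided by the mean of its baseline window (default: the first 10 s of
  the recording, before the first trial; configurable) and converted to
  an optical-density change $\Delta OD(t) = -\log_{10} I(t)/\bar I_0$.
  Base-10 is the standard OD convention; natural log is available via
  `od_base` and is self-consistent on both the forward and inverse paths,
  so round trips hold under either.
* **Differential pathlength factor.** Photons travel farther than the
  2.5 cm source–detector separation; the DPF multiplier is evaluated
  from the general five-term equation in age and wavelength,
  $223.3 + 0.05624\,A^{0.8493} - 5.723\times10^{-7}\lambda^3 +
  0.001245\lambda^2 - 0.9025\lambda$, valid across the near-infrared
  window (expected range here roughly 5–7).
* **Modified Beer–Lambert inversion.** Per sample the $2\times2$ linear
  system $\Delta OD_\lambda = (\varepsilon_{\lambda,HbO}\,\Delta HbO +
  \varepsilon_{\lambda,HbR}\,\Delta HbR)\, d\, DPF_\lambda$ is solved for
  $(\Delta HbO, \Delta HbR)$ in µM. Extinction coefficients default to a
  standard compiled hemoglobin-spectra pair at 730/850 nm, stored
  explicitly in the configuration (cm⁻¹ µM⁻¹) so that the synthetic
  forward model and the inversion always share one source of truth; the
  partial volume factor is taken as 1, so concentrations are relative.

Filtering and detrending follow, in the fixed order normalize → ΔOD →
MBLL → low-pass → detrend:

* **Butterworth low-pass, order 10, cut-off 0.1 Hz.** Implemented as
  bilinear-transformed second-order sections with step-matched initial
  conditions (unit DC gain; a constant input passes unchanged). Because
  a tenth-order causal IIR filter delays the signal appreciably, the
  default applies the filter forward and backward (zero phase) so trial
  latencies — CAS in particular — are unbiased; a causal single-pass
  mode is available (`zero_phase = FALSE`). This is a documented
  deviation: the study states only "IIR, order 10". The digital
  magnitude response satisfies the closed form
  $|H(f)| = (1 + (\tan(\pi f/f_s)/\tan(\pi f_c/f_s))^{2n})^{-1/2}$,
  which the tests check at 0.5 Hz.
* **Piecewise linear detrending.** The study names no segmentation; the
  default removes an independently fitted least-squares line from each
  contiguous 60-s segment (`detrend_segment_s`), short trailing
  remainders merged into the last segment. Sixty seconds is long against
  the 11-s trial window (so responses are not flattened) and short
  against slow drift.

## 2. Trial screening and block averaging

Trials are the 11-s windows following each stimulus onset (22 samples at
2 Hz; half-open, onset sample included, 0-based indexing). Three
criteria screen each trial of each channel:

1. *Anticorrelation*: Pearson $r(HbO, HbR) < 0$ over the window — the
   hemodynamic signature of activation is an HbO rise mirrored by an HbR
   dip.
2. *Oxygenation dominance*: mean HbO > mean HbR.
3. *Positivity*: mean HbO > 0.

"Negative HbO values" is read as a negative trial-mean: rejecting any
trial containing a single negative sample would discard nearly all
physiological baseline-relative trials. A stricter `positivity_mode =
"all_samples"` is available. Zero-variance windows, where the
correlation is undefined, are rejected with reason `"degenerate"` rather
than raising an error. A channel is dropped when its rejected fraction
is **at least** 0.80 — the source sentence ("more than 80% or more") is
ambiguous between strict and inclusive; inclusive is chosen and the
threshold is configurable. A subject is dropped when all 16 channels
are dropped. Averages are pointwise means over retained trials only.
Font and Low-Complexity trials pass through the identical screen when
the task-load comparison is run; the study is silent on this and
uniformity is the only defensible choice.

## 3. The eleven features

Moment features of the averaged HbO window use population ($1/n$)
moments — the variance definition is explicitly $\frac1n\sum(HbO_i -
HM)^2$, and skewness/kurtosis follow the same convention (Fisher $g_1$,
excess $g_2$; a normal signal scores 0). Curve features come from the
*activity curve*, the positive deflection around the window's maximum:

* the **peak** is the first-occurring argmax;
* the **start** is the nearest sample left of the peak where the signal
  is non-positive or turns back upward (a local minimum), defaulting to
  the window edge; the **end** is symmetric on the right. The source
  defines the curve only pictorially, so this zero-crossing-or-turning
  rule is stated explicitly and brute-force tested;
* CSL and CSR are the signed two-point slopes start→peak and peak→end
  (µM/s); CA is the trapezoidal integral of the signal (not
  signal-minus-baseline) between start and end (µM·s); CP the peak
  amplitude (µM); CAS the start time (s); CF the full width at half the
  peak amplitude, by linear interpolation of the two half-peak crossings
  nearest the peak, clipped to the window edge (flagged) when a crossing
  is absent. An all-nonpositive or constant window yields a degenerate
  curve: slopes, CA and CF are 0 by definition and flagged.

**HDFT** is the magnitude $|c_n|$ of discrete Fourier coefficients
$c_n = \sum_k HbO(k)\,e^{-2\pi i k n/N}$ at the bins nearest 0.02, 0.05
and 0.09 Hz. It is computed on the *full-length filtered channel
signal*, not the 11-s average: a 22-sample DFT has 0.0909 Hz resolution
and cannot represent the stated 0.01–0.1 Hz band at all. This is the
most consequential ambiguity in the source description, resolved here in
the only physically realizable way. Three coefficients are used (the
methods statement); the discussion elsewhere mentions four — `n_coeff`
is configurable and HDFT always counts as *one* feature in subset
enumeration, preserving the 11-feature / 2047-subset arithmetic.

Temporal analysis averages each feature element-wise across retained
channels; spatio-temporal analysis keeps the per-channel values with
explicit `NA` for pruned channels.

## 4. Classification and subset search

TBI is the positive class. Each candidate feature subset is scored by
repeated random subsampling: a stratified split draws 70 % of each class
(rounded to nearest, at least one test member per class — so the 31/30
cohort gives 22+21 training and 9+9 test subjects), a classifier is
trained on the subset's columns and evaluated on the held-out subjects,
and accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
specificity = TN/(TN+FP) are averaged over runs (study protocol: 1000;
tests scale down to 100–200 and say so). Run seeds derive from the
master seed only, so all subsets see identical splits — comparisons are
paired (common random numbers) and any subset's score is exactly
reproducible. Runs whose training set degenerates are excluded and
counted; more than 1 % failures aborts the evaluation.

The default classifier is binary CART: Gini impurity, grown to purity
with no pruning (the classical default; no hyperparameters are given in
the source), midpoint thresholds, ties broken deterministically toward
the lowest feature index then lowest threshold — which makes duplicated
columns provably inert. Missing entries are routed, during training, to
the child that minimizes the weighted impurity; the learned direction is
reused at prediction. This is what lets the spatio-temporal analysis use
incomplete channel sets natively. LDA (two-class, pooled covariance
with a small ridge for singular cases) and a polynomial-kernel C-SVC
(degree 3, cost 1, SMO-trained) serve as comparison classifiers; both
mean-impute missing values from training columns since neither handles
them natively. Every model exposes a continuous positive-class score
(tree: leaf positive fraction; LDA: discriminant value; SVM: margin) for
ROC analysis.

The wrapper search evaluates all $2^p - 1$ subsets and reports per-size
optima and the global optimum; ties prefer the smaller subset, then
lexicographic order. ROC curves are averaged vertically: per run the
operating-point path over all score thresholds is interpolated onto a
101-point false-positive-rate grid (linearly between distinct FPRs, so a
single run's area equals its standard empirical AUC), TPRs are averaged
across runs, and AUC is the trapezoid of the averaged curve. Runs with
constant scores contribute the chance diagonal.

## 5. The synthetic cohort: what it emulates, what it does not

The generator is the package's stand-in for the study's undeposited
recordings (31 healthy, 30 TBI). Its stated world:

* **Paradigm**: 33 trials per condition (Font, Low, High complexity),
  5 s each, inter-stimulus intervals uniform on [5, 7] s, 15-s lead-in.
  Note the arithmetic: 99 such trials need ≈ 18–20 min, although the
  source describes a 15-min session; the counts and ISI are kept and the
  default session is 1200 s (`generate_schedule` refuses designs that do
  not fit, naming the required minimum).
* **Response model**: the canonical double-gamma HRF (peak ≈ 5–6 s,
  undershoot ≈ 16 s, ratio 1/6), scaled by per-channel amplitudes and
  stretched per group — no response model is described in the source, so
  the field-standard generative stand-in is used, validated only by
  parameter recovery.
* **Group effect defaults** (`effect_spec()`): healthy high-complexity
  peak 0.8 µM versus TBI 0.4 µM, a 1.5× healthy boost on left-hemisphere
  channels 1–8 (the montage's stand-in for left frontopolar cortex), and
  broader TBI responses (width 1.4×). Between-subject variability is a
  subject-level log-normal gain (σ_log = 0.4 — coupling and anatomy act
  on all channels together) plus 0.3 µM per-channel noise. These produce
  cohort-level accuracies in the 0.7–0.9 range at realistic sample
  sizes, i.e. a separable-but-noisy world, not a trivially separable
  one.
* **Nuisance components** (`noise_params()`): white noise (0.05 µM SD),
  per-channel linear drift (±0.05 µM/min), three oscillations inside
  0.01–0.1 Hz (0.02/0.05/0.09 Hz, 0.05 µM), a ≈0.1 Hz Mayer-like wave
  and a 0.25 Hz respiratory wave. Cardiac pulsation (~1 Hz) is omitted
  deliberately: at 2 Hz sampling it would alias unpredictably.
  HbR is coupled as $-r\,\Delta HbO$ ($r = 1/3$) plus independent noise,
  so clean trials satisfy the anticorrelation screen *by construction*;
  motion-artifact trials (5 % by default) receive an additive spike and
  locally sign-flipped coupling and so fail it, also by construction.
* **Forward optics**: latent concentrations go through the same MBLL
  configuration used for inversion, to intensities
  $I = I_0\,10^{-\Delta OD}$ with $I_0 = 1000$ (arbitrary units; ΔOD is
  ratio-based). Ages are drawn from group-specific truncated normals
  (healthy 30.8 ± 8.1, TBI 37.8 ± 11.6, clipped to [18, 55]) so the DPF
  varies realistically.

Not emulated: scalp/skull partial-volume effects, channel-specific
optode-coupling physics, eye blinks, or any true channel-to-anatomy
registration — the left/right channel split is a declared synthetic
layout. Consequently a green test establishes that the *pipeline*
recovers what was planted under this world's assumptions; it cannot
establish anything about real TBI physiology, and the study's printed
table values (computed on the undeposited human recordings) are not
reproduction targets.

## 6. Numerical choices and degenerate inputs

* Forward/inverse MBLL round trips are exact to < 10⁻⁹ µM at zero noise
  (tested); the extinction matrix is validated as well-conditioned at
  configuration time.
* Filtering requires a signal longer than three times the section count;
  shorter inputs fail with the minimum length named.
* HDFT requires at least two periods of the lowest band frequency
  (400 samples at 2 Hz); shorter inputs fail rather than silently
  returning unresolvable bins.
* Trials that would extend past the recording end are skipped with a
  warning, not truncated.
* Classifier training requires two members of each class; the stratified
  split guarantees a non-empty test set per class, which keeps all three
  metric denominators positive.
* Empty populations, channels with zero contributors, and features with
  more than 90 % missing entries are reported as not-evaluable rather
  than raising errors mid-cohort.

## 7. Known limitations

Flat repeated subsampling rewards subsets that fit a small cohort's
quirks; selecting the maximum over 2047 subsets is optimistically biased
and no nested validation corrects for it here (deliberately — the method
is implemented as described). The null-calibration tests therefore judge
chance-level behaviour against a subject-level binomial scale
($\sqrt{0.25/n}$): the subsampling runs reuse the same subjects, so the
cohort — not the run count — is the effective sample size. Greedy
search, HbR/total-hemoglobin features and zero-padded DFT variants are
out of scope.
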