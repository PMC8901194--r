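---
title: "Methods: non-negative short-channel regression and test-retest analysis for fNIRS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: non-negative short-channel regression and test-retest analysis for fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, numerical choices and known limitations
behind `nirscr`. It is the reference for every decision that the function
documentation states without argument.

## The measurement model

A long-separation fNIRS channel (~30 mm source-detector distance) records
light that traversed scalp *and* cortex; a short-separation channel (7.5 mm)
records scalp only. The measured intensity `I(t)` at wavelength λ relates to
hemoglobin concentration changes through the modified Beer-Lambert law:

```
OD(λ, t) = -log10(I(t) / I_ref)
         = [ ε_O2Hb(λ) ΔO2Hb(t) + ε_HHb(λ) ΔHHb(t) ] · DPF(λ) · L
```

with `L` the source-detector distance (cm), `DPF` the differential
pathlength factor (defaults 6.2, 6.2, 5.9, 5.5 at 774, 817, 865, 892 nm) and
ε the base-10 molar extinction coefficients (cm⁻¹ M⁻¹). With four
wavelengths and two chromophores the inversion is an overdetermined linear
system, solved per sample and channel in the least-squares sense.

**Extinction table.** The four wavelengths sit between the tabulated grid
points of the standard compiled hemoglobin absorption spectra (the OMLC
compilation); `extinction_default()` ships linear interpolations of that
table and `mbll_params()` accepts overrides. The simulator's forward model
and the inversion share one table, so simulation round trips are exact by
construction and any table error cancels in all synthetic-data validation.
`I_ref` is the mean intensity over a rest window, by default the 120 s
leading baseline.

## Activation model (GLM with non-negative nuisance weights)

Per long channel and chromophore the concentration series is modeled as

```
y = Σ_c  β_c  (boxcar_c ⊗ h)  +  derivative terms  +  Σ_j w_j s_j  +  β_0 + ε,
          w_j ≥ 0
```

* `h` is the canonical double-gamma HRF: response gamma with mode 6 s minus
  an undershoot gamma with mode 16 s at ratio 1/6, truncated at 32 s,
  peak-normalized. The task regressor `boxcar ⊗ h` is scaled to unit peak so
  `β_c` reads directly in μM.
* The temporal derivative (finite difference of a 1 s onset shift) and the
  dispersion derivative (finite difference of the response-gamma scale,
  step 0.01) absorb latency and width deviations. Both are orthogonalized
  against the canonical column (Gram-Schmidt, then unit-normalized), so they
  soak up misfit variance without touching the amplitude interpretation of
  `β_c`. They do not enter any contrast: activation strength is the t-value
  of the canonical coefficient alone.
* The nuisance regressors `s_j` are all mean-centered short-channel series
  of the **same chromophore** (O2Hb on O2Hb, HHb on HHb; cross-chromophore
  regression is not supported), filtered identically to the data and
  admitted only if they pass the 12 dB cardiac-content quality check.
  Their weights are constrained non-negative: scalp physiology can only add
  to a long channel, and allowing negative weights lets the regression eat
  genuine cortical signal. Task and constant columns stay unconstrained.
* Nuisance weights are fitted **jointly** with the task regressors in one
  constrained least-squares problem (not as a pre-regression step).

**Solver.** The mixed problem — some columns free, some constrained — is
solved exactly with an active-set method in the Lawson-Hanson style: the
free block is always in the solve; constrained columns enter by largest
positive gradient and leave through feasibility line steps. Termination at
the KKT point is checked in the test suite against exhaustive enumeration of
all sign supports.

**Degrees of freedom.** `σ²` uses `dof = n − (free columns + active nuisance
columns)`: a clamped (zero-weight) nuisance column consumed no fitting
freedom. This follows standard active-set practice; the baseline-threshold
calibration property (fresh-null exceedance ≈ 5%) validates the convention
empirically.

**t-values.** `t = β_c / sqrt(σ² [(X'X)⁻¹]_cc)` on the design restricted to
free plus active columns. Zero-residual (noise-free) fits are capped at 1e6
with a warning so tables stay finite.

## Baseline-derived thresholds and responder labeling

To decide whether a t-value indicates activity rather than rest physiology,
the full 30-trial protocol is placed at random temporal shifts inside rest
data and refitted; the 95th percentile of the absolute null t-values is the
threshold (absolute values, since the null is sign-symmetric). Shipped
defaults are 30 (SCR) and 22 (NR), the published levels for the wearable
device class this montage models; thresholds derived from synthetic rest are
lower and internally calibrated, which is what the tests check. For the
derivation we use rest data 2.5× the protocol length and 1000 placements so
that placements are only weakly dependent and the exceedance of a fresh null
sample stays within 5% ± 1.5%.

A subject is a **strong responder** if the maximal t-value per run (over
channels and conditions), averaged over the four runs, strictly exceeds the
threshold; a value exactly at the threshold is weak.

## Preprocessing choices

* **Band-pass.** Windowed-sinc (Hamming) FIR of order 1000 with cutoffs
  0.015 and 0.35 Hz, applied zero-phase by forward-backward convolution on
  reflection-padded signals (FFT-based). The kernel is mean-corrected so DC
  is nulled exactly. Measured response: < ±0.1 dB ripple over 0.05–0.3 Hz,
  0° phase, −140 dB at 1 Hz, −125 dB at 0.5 Hz, and ≈ −33 dB at 0.005 Hz —
  at 8.98 Hz sampling an order-1000 kernel cannot attenuate 0.005 Hz much
  further because the transition band (~0.03 Hz) is wider than the distance
  to the cutoff. Task regressors are filtered with the same kernel as the
  data, which keeps amplitude recovery unbiased (exact in the noise-free
  limit).
* **Motion correction.** Artifact segments are detected where the 1 s
  moving-window sd exceeds 3× the median moving sd; within a segment a
  smoothing-spline trend is subtracted and the segment plus all subsequent
  data are re-anchored to the preceding clean level, removing both spikes
  and persistent baseline steps. Limitation: level re-anchoring across an
  artifact is only identifiable when the background varies slowly relative
  to the ~1 s anchor windows; fast oscillations passing through an artifact
  cannot be disambiguated from it. Correction runs on optical density,
  per channel and wavelength, before the MBLL inversion.
* **Ordering constraint.** The quality metrics (short-channel cardiac
  content, Mayer amplitude) are computed on the *unfiltered* hemoglobin
  series — the 0.35 Hz low-pass would erase the pulse band they rely on.

## Quality metrics

Band powers use a Welch estimator (Hann window, 60 s segments, 50% overlap).
The short-channel quality index is `10·log10` of cardiac band power
(0.6–2 Hz) over background power (2–4 Hz; the band between the pulse and the
4.49 Hz Nyquist — the upstream reference does not pin this choice, so it is
a documented config). The Mayer-wave amplitude is the median over long
channels of the O2Hb power ratio 0.07–0.14 Hz : 0.6–2 Hz, a scale-free
quantity. Subject screening uses the mean raw intensity of the long channels
(≥ 0.06 V); the 0.06 V ↔ 40 dB correspondence is hardware-specific, so both
thresholds are independent configuration values.

## Reproducibility statistics

Between-session agreement is computed on the contralateral M1 ROI (ROI 1 for
right-hand, ROI 5 for left-hand grasping; an ROI value is the mean of its
two overlapping long channels), runs averaged within session:

* Pearson r with Fisher-z 95% CI (ROI-level values, matching the ROI
  averaging used everywhere else);
* ICC(2,1) and ICC(2,k), two-way random effects, absolute agreement, from
  the ANOVA mean squares, with the canonical F-based confidence intervals
  (Satterthwaite degrees of freedom for the single measure; the average
  measure CI by the Spearman-Brown step-up). Interpretation bins: poor
  (< 0.40), fair (0.40–0.60), good (0.60–0.75), excellent (0.75–1.00).
* MAE% = 100 · mean|t₂ − t₁| / range. "Range of observed values" is read as
  the **pooled** two-session range per analysis block (the per-session
  alternative is asymmetric in the sessions, which the metric is not meant
  to be).

## Pseudo-online classification

The BCI chain is strictly causal: a forward-only high-pass (Chebyshev II,
order 2, 0.005 Hz, 20 dB stop-band) then low-pass (Butterworth, order 4,
0.35 Hz); sample-wise SCR by normalized least-mean-squares with projection
onto w ≥ 0 (step 0.01). The NLMS update is normalized by an exponentially
smoothed regressor power (99%/1%) rather than the instantaneous power, which
vanishes at zero crossings and would destabilize the update.

Features per long channel and 16 s trial window: amplitude (window mean
minus the value at onset — "amplitude" is otherwise underspecified, and the
baseline-referenced mean is robust to the window's slow offsets), slope
(least-squares line, per second), and the mean of the CBSI-combined trace
`x = (ΔO2Hb − σ·ΔHHb)/2`, `σ = sd(ΔO2Hb)/sd(ΔHHb)` per window.

The classifier is an L1-regularized linear (lasso-penalized logistic) model
fitted with `glmnet`: joint training and feature selection, features
standardized with training statistics, penalty chosen by stratified seeded
5-fold cross-validation over 10 log-spaced values in [1e−3, 1e2]. An
L1-penalized linear decision rule is what the sparsity argument requires;
the logistic loss stands in for the hinge loss with the same selection
behaviour, which is what the permutation-null, separability and
duplicate-feature tests pin down. Evaluation is train-on-run-1 /
test-on-run-2 with one decision per trial. The display convention for
significance is the 70% line; the exact one-sided binomial threshold at
α = 0.01 for 30 trials is 22/30 ≈ 73.3%, and `significance_line()` computes
it for any trial count.

## The synthetic-data generator

`simulate_study()` emulates the test-retest study design this package
targets: 15 subjects (9 strong, 6 weak responders) × 2 sessions × 2 runs;
30 trials (15 left / 15 right, seeded random order) of 16 s
with ISIs uniform on 15–24 s, 120 s leading and 60 s trailing rest, sampled
at 8.98 Hz.

Signal construction per run:

* Cortical response per ROI: unit-peak canonical-HRF regressor × amplitude.
  Spatial pattern per condition: contralateral M1 at full amplitude
  (0.26 μM O2Hb right hand, 0.21 μM left hand — group-level response sizes
  of this task class), adjacent contralateral premotor ROIs at 0.5×,
  ipsilateral M1 at 0.2×, rest silent. ΔHHb = −0.4 × ΔO2Hb (one free
  parameter matching the reported ≈0.26/−0.12 ratio).
* One superficial source per hemisphere, shared by its short and long
  channels with channel-specific gains — the premise of multichannel SCR is
  exactly this partial spatial correlation. Components (μM at the scalp):
  Mayer oscillation 0.5 × subject factor at 0.095–0.11 Hz with a slowly
  modulated amplitude (±30% at 0.013 Hz) so filters and regressors face a
  narrow-band stochastic process, not a pure tone; cardiac sine 1.0 at
  1–1.3 Hz (typical scalp pulsation); random linear drift (sd 0.3 over the
  run); AR(1) background (sd 0.1, 5 s correlation time). Long channels
  receive the superficial signal at share 0.4 ± 0.1 (no published value for
  this device exists; 0.3–0.6 is the plausible range and 0.4 is the fixed
  default), short channels at gain 1.0 ± 0.1.
* Forward MBLL to four wavelengths at the subject's raw intensity level
  (lognormal channel/wavelength jitter), plus an additive 0.6 mV sensor
  noise floor, which places the 40 dB raw-intensity SNR at 0.06 V. Short
  channels run at 10× the subject's long-channel light level — 7.5 mm paths
  detect far more light — which is what makes their cardiac content
  resolvable (≥ 90% pass 12 dB under default conditions).
* Weak responders: five subjects with raw intensity 0.03–0.055 V (below the
  screening threshold) and ~0.3× response amplitude, one subject with
  adequate optics (0.12 V) but a near-absent response (0.08×) and high
  Mayer activity — the generator's counterpart of the low-t/high-signal
  outlier pattern. Session effects are multiplicative amplitude factors
  ~N(1, 0.08).

**What the generator does not emulate** (and hence what green tests do not
show about real data): photon transport and partial-volume effects, motion
artifacts (none are injected by default; the motion-correction tests inject
their own), task-evoked systemic activity (scalp responses time-locked to
the task), inter-channel differences in HRF shape or latency, habituation
across runs, and optode re-placement error between sessions. Simulated
t-values are therefore larger than typical empirical ones; all downstream
claims are validated as directional/calibration properties, not as value
reproductions.

## Problem sizes

The test suite fits one full-size study (15 × 2 × 2, ~1210 s runs), derives
baseline thresholds from 2 × 1000 placements on a ~52 min rest series, and
uses a 3-subject study with 10-trial runs for mechanics and determinism
checks; `scripts/acceptance.R` repeats the full-size computations from
scratch. A complete study simulation plus activation analysis takes about
two minutes on one CPU; the entire acceptance script about ten.

## Known limitations

* The SNIRF dialect stores the authoritative montage as a JSON metadata tag
  (plus standard probe/stim groups); third-party SNIRF files without that
  tag are not ingested. No vendor fiber formats, no 10–20 registration.
* Channel ordering of the default montage is fixed but arbitrary; no device
  convention is published.
* No prewhitening: GLM errors are treated as white within the pass band.
  The null-calibration property shows the thresholds absorb this on
  band-limited data; autocorrelation-robust inference is out of scope.
* ICC confidence intervals assume the normal two-way model; with n = 15
  subjects they are wide, as the reported intervals show.
* `baseline_threshold()` needs rest data longer than the protocol; deriving
  it from the 120 s baselines alone is not possible.
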