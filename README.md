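# nirscr

Short-channel regression and test-retest reproducibility analysis for
functional near-infrared spectroscopy (fNIRS).

## The problem

fNIRS measures task-evoked changes of oxy- and deoxyhemoglobin
(ΔO2Hb / ΔHHb, in μM) through the scalp with long-separation optode pairs
(~30 mm). Those channels see cortex *plus* scalp: Mayer waves (~0.1 Hz blood
pressure oscillations), cardiac pulsation, and slow drifts contaminate the
hemodynamic response and make single-subject activation estimates poorly
reproducible across days. Short-separation channels (7.5 mm) see essentially
only scalp, so scalp physiology can be regressed out of the long channels
("short-channel regression", SCR).

`nirscr` implements a complete analysis chain for block-design motor-task
studies measured with a bilateral 8-optode montage (16 long + 8 short
channels, 8 regions of interest, four wavelengths 774/817/865/892 nm,
~8.98 Hz):

* **Simulation** of whole test-retest studies (15 subjects × 2 sessions ×
  2 runs of 30 grasping trials) with known ground truth: lateralized
  cortical responses, hemisphere-shared superficial physiology, per-subject
  raw signal strength and responder status.
* **Preprocessing**: spline motion correction, modified Beer–Lambert
  inversion (4 wavelengths → 2 chromophores, DPF 6.2/6.2/5.9/5.5), zero-phase
  FIR band-pass 0.015–0.35 Hz (order 1000).
* **Activation estimation** — the core. Per channel GLM
  `y = X β + ε` where `X` holds, per condition, the canonical double-gamma
  HRF regressor plus orthogonalized temporal and dispersion derivatives, a
  constant, and (for SCR) all quality-passing short channels as nuisance
  regressors constrained to **non-negative** weights:

  `min_β ‖y − Xβ‖²  s.t.  β_j ≥ 0 for nuisance j`

  solved by an exact active-set method (multichannel non-negative SCR,
  "GLMmultiSS"). Activation strength is the t-value of the canonical
  regressor; significance thresholds are derived from GLM fits of the
  protocol placed at random shifts in rest data (shipped defaults t ≥ 30
  for SCR, t ≥ 22 for unregressed data), and subjects are labeled
  strong/weak responders by their run-averaged maximal t.
* **Quality metrics**: raw intensity / SNR screening (0.06 V ↔ 40 dB),
  cardiac-content short-channel quality (12 dB), Mayer-wave amplitude
  (band-power ratio 0.07–0.14 Hz over 0.6–2 Hz).
* **Reproducibility**: between-session Pearson correlation, ICC(2,1) /
  ICC(2,k) (two-way random, absolute agreement) with 95% CIs, and MAE%
  at the contralateral M1 ROIs.
* **BCI classification**: pseudo-online left-vs-right decoding with causal
  filtering, sample-wise adaptive non-negative SCR, amplitude/slope/CBSI
  features, and an L1-regularized linear classifier with 5-fold CV.

## Worked example

Simulate one strong responder's run and estimate activation with and without
short-channel regression:

```r
library(nirscr)
cfg <- sim_config(n_subjects = 1, seed = 7)
set.seed(7)
profile <- subject_profiles(cfg, n_strong = 1, n_weak = 0)[[1]]
sim <- simulate_recording(profile, cfg, session = 1, run = 1, seed = 11)
fit <- fit_activation(sim$recording)
m1 <- subset(fit$roi, chromophore == "o2hb" & roi %in% c(1, 5))
m1[order(m1$tag, m1$condition), ]
```

```
   subject session run tag chromophore condition roi     t   beta
3        1       1   1  NR        o2hb      left   1  11.1 0.0490
35       1       1   1  NR        o2hb      left   5  72.6 0.3126
7        1       1   1  NR        o2hb     right   1  85.5 0.3832
39       1       1   1  NR        o2hb     right   5  14.0 0.0610
4        1       1   1 SCR        o2hb      left   1  27.2 0.0607
36       1       1   1 SCR        o2hb      left   5 173.3 0.3185
8        1       1   1 SCR        o2hb     right   1 172.6 0.3898
40       1       1   1 SCR        o2hb     right   5  41.5 0.0774
```

The activation is lateralized as expected — right-hand grasping drives ROI 1
(left M1), left-hand ROI 5 (right M1) — and regressing the short channels
roughly doubles the t-values while the amplitude estimate (`beta`, μM)
matches the generating truth (0.390 μM at ROI 1 / right hand, 0.315 μM at
ROI 5 / left hand) more closely than the unregressed fit. The run's quality
report for this subject: mean raw intensity 0.093 V (screening pass), Mayer
amplitude 0.134, and 8/8 short channels above the 12 dB cardiac-content
threshold.

Study-level analyses follow the same pattern: `simulate_study()` →
`activation_table()` → `reproducibility_report()` (ICC/correlation/MAE% per
chromophore × condition × tag) and `bci_evaluate()` for run-1 → run-2
classification.

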