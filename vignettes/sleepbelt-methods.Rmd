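---
title: "sleepbelt: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sleepbelt: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepbelt)
```

# Scope

`sleepbelt` implements the analysis side of wearable-belt sleep-apnea
screening: paired whole-night ECG and thoracic-excursion recordings from a
chest belt and from reference polysomnography (PSG) are quality-filtered,
reduced to heart-rate-variability (HRV) and breathing-rate-variability
(BRV) feature vectors, and used for device-agreement analysis,
apnea-severity classification and multi-night repeatability estimation.
Because no public dataset of this kind exists, the package ships a
synthetic-cohort generator that serves as the test bed for every
downstream stage. The belt hardware itself, PSG scoring of the
apnea-hypopnea index (AHI -- it enters only as a label), oximetry and
sleep staging are all out of scope.

# The synthetic world

The generator states a world and the tests measure the pipeline against
it; its parameters are fixed once and are not tuned to test outcomes.

**Severity.** Each virtual subject carries an AHI drawn from a log-normal
distribution calibrated to a referred sleep-clinic population: median 33
events/h, inter-quartile range 16--58 (`sample_ahi()`). Apnea events are
scheduled (`schedule_apneas()`) with a Poisson count at the AHI rate,
non-overlapping placement by uniform spacing of the free time, and
durations of 10 s (the standard scoring floor) plus an exponential tail
with 12 s mean, capped at 60 s. A thinned Poisson process was rejected
because thinning undercounts at high AHI; the spacing construction keeps
the realized rate equal to the nominal AHI, which the Monte-Carlo rate
test verifies to 3 standard errors.

**ECG.** The beat-to-beat RR track (`synthesize_rr_track()`) superposes,
on a 1000 ms baseline (60 bpm default): respiratory sinus arrhythmia
(3.5% modulation at the breathing frequency, yielding HF power), a 0.095
Hz oscillation (2.5%, Mayer-wave band, yielding LF power), a 0.01 Hz
drift (2%, VLF), and the classical apnea signature -- bradycardia ramping
over each event with amplitude 12--22% growing with event duration,
followed by a tachycardia overshoot decaying over the 15 s after the
event. This cyclic variation is what makes HRV features informative of
AHI; its magnitudes are the generator's own choice (plausible for
referred patients, large enough to matter, small enough to keep RR inside
333--2000 ms, which is enforced by clamping). The waveform
(`synthesize_ecg()`) places a sum-of-Gaussians PQRST template (ECGSYN
style: P, Q, R, S, T deflections; R amplitude 1 mV) at each beat, plus
baseline wander and white noise scaled by `noise_level`.

**Breathing.** Cycle durations (`synthesize_breath_track()`) modulate a
60/`base_bf` baseline: 45% slowing during events, 25% acceleration in the
15 s recovery, clamped so rates outside events stay within the 5--50
breaths/min plausibility band. Excursion amplitude drops to 15% during
obstructive events (persisting paradoxical effort), to 2% during central
events, and rebounds to 125% during recovery. Each cycle is rendered
trough-to-trough as a raised-cosine with a distinct inhale fraction
(~0.38), so onset, inhale duration and amplitude are all recoverable.

**Devices and artifacts.** Belt and PSG records of one night share one
event schedule and one RR/breath track; only rendering noise differs
(PSG at 0.3 times the belt's `noise_level`). `inject_artifacts()`
replaces a requested fraction of a record with contiguous high-amplitude
noise blocks of geometric length (30 s mean), because real belt failures
arrive as sustained stretches, not isolated samples.

**Feature-level cohorts.** Classifier and repeatability validation use
`simulate_feature_cohort()`, which draws the 22 features directly as
`loading * z(log AHI) + subject_effect + night_noise`. With
`effect_size = 0` every feature's intra-class correlation equals the
stated `icc` exactly, giving the repeatability module a known truth; with
the default effect size both channels carry severity signal, giving the
classifier a separable cohort. Rendering waveforms would add hours of
compute without changing what these tests measure.

**What a green test does not establish.** The generator reproduces the
*structure* real analyses rely on (cyclic variation, template-stable
morphology, artifact stretches, within-subject correlation), not the
messiness of real signals: no ectopy, no electrode pop, no body-position
effects, no REM/NREM differences, and a noise model far simpler than
textile-electrode reality. Green acceptance therefore certifies the
pipeline's internal correctness and statistical behavior, not clinical
performance.

# Signal-quality filtering

**ECG.** R-peaks come from a derivative-energy detector (Pan-Tompkins
family) with block-adaptive thresholds and a 200 ms refractory period.
Quality is judged on consecutive 15 s segments: each beat's QRS and PQRST
complex is correlated against the segment's reference complex (the
element-wise median of the segment's complexes, aligned on the R sample,
native rate, no time warping), the segment r is the mean per-beat Pearson
r, and the segment is accepted when the better of the QRS and PQRST r
strictly exceeds 0.98. Either complex suffices, since they are treated as
alternative acceptance routes. If correlation fails, physiological
plausibility rescues the segment when every RR lies within 333--2000 ms
(180 down to 30 bpm) and within 33% of the segment median. Window widths
are not fixed by convention, so they are configuration: QRS = R ± 60 ms,
PQRST = R − 250 ms to R + 400 ms; windows may span segment borders;
segments with fewer than 3 usable beats have undefined r and fall to the
plausibility route. An RR interval belongs to the segment containing its
ending R-peak.

**Breathing.** 32 s segments; each cycle is time-normalized phase-wise
(inhale and exhale resampled separately to 40- and 60-point grids) and
amplitude-normalized to [0, 1] -- this adjusts the comparison for total
cycle duration, inhale-phase duration and excursion amplitude without
inventing a warping model. Acceptance is *inclusive* at r ≥ 0.75,
whereas the ECG rule is strict at r > 0.98; the asymmetry is deliberate
and both thresholds are parameters. Breath-to-breath intervals outside
5--50 breaths/min are excluded regardless; boundary rates are kept, with
a 1 ns interval tolerance so the printed boundary (exactly 50/min) is not
lost to floating point. Segments are non-overlapping, as for ECG.

# Variability features

Eleven features per channel, identical code for RR (ms) and
breath-to-breath (s) series:

* time domain: SDNN (SD of intervals), pNN50 (share of successive
  differences > 50 ms), rMSSD, IRRR (inter-quartile range), MADRR
  (median interval), HRVi (triangular index, count / max histogram bin,
  bin width 1/128 s).
* frequency domain: ULF (0--0.003 Hz), VLF (0.003--0.03), LF
  (0.03--0.15), HF (0.15--0.4) and LF/HF, from short-time Fourier
  transforms of the interval series cubically interpolated to 4 Hz
  (standard HRV practice), 300 s Hann windows, non-overlapping by
  default, mean over windows (no single aggregation convention exists;
  mean is used and exposed).

Numerical choices worth knowing:

* A 300 s window cannot resolve the ULF band edge (1/300 Hz > 0.003 Hz),
  so per-window ULF is near zero by construction; the reported `ulf` is
  instead estimated from the whole-night periodogram. Per-window values
  remain available from `band_powers()`.
* Windows overlapping a quality gap longer than 15 s are skipped rather
  than interpolated across; shorter gaps are bridged by the spline.
* For BRV, pNN50's 50 ms threshold is kept literally (the features are
  defined by swapping the signal, not by rescaling), but it is a
  parameter because 50 ms is physiologically tiny for breaths. The HRVi
  bin width for BRV scales with the ratio of the median interval to a
  nominal 800 ms RR so the index stays comparable across channels.
* Band-edge bins: a bin at frequency f belongs to the band with
  lo < f ≤ hi, so the four bands partition (0, 0.4] Hz exactly and their
  powers sum to the window's total power there (tested to 1e-6).

# Agreement, classification, repeatability

**Agreement.** Whole-night mean instantaneous heart and breathing rates
are arithmetic means of per-interval rates (60000/RR, 60/BB) -- "mean
instantaneous", not the rate of the mean interval; both conventions are
exposed. Bland-Altman differences are belt − PSG (positive bias = belt
reads higher), bias CI by t-interval, limits of agreement at bias ±
1.96 SD with CIs using the approximate standard error sqrt(3 sd²/n)
(the approximate form is the textbook default; the exact formula adds
nothing at these sample sizes).

**Classification.** AHI is dichotomized at a cohort quantile (default
the median; ties go to the negative class, strict >). The SVM is a
C-classification machine with RBF kernel, cost 1 and gamma = 1/(p · var)
-- the field's standard defaults, since nothing in the problem fixes
the hyperparameters -- solved exactly as the dual quadratic program with
`quadprog` (no SVM library is assumed present). Class costs are
rebalanced inversely to class frequency: pooled leave-one-out decision
scores are otherwise biased by each fold's forced imbalance, which drags
null-data AUC far below 0.5; with balancing the permutation null sits at
~0.5 as it should. Features are standardized on training rows only,
refitted in every LOOCV fold. ROC curves are empirical; AUC is the
Mann-Whitney statistic (ties half-counted); the 95% CI is DeLong's,
clipped to [0, 1]; the reported sensitivity/specificity sit at the
Youden-optimal point, the usual rule when none is imposed.

**Repeatability.** R = between-subject variance over total variance from
a Gaussian random-intercept model fit by REML with `lme4` (the rptR
package, an lme4 wrapper, is the usual interface; only its Gaussian case
is needed because all features are continuous). CIs are seeded parametric
bootstraps (default 1000 draws). On balanced designs the REML components
coincide with one-way ANOVA method-of-moments estimates, which the tests
use as an independent oracle. Channel summaries are the median and IQR of
R across the 11 features per channel; all 11 enter the summary.

# Open choices made here

* Whether a segment passing QRS-r but failing PQRST-r counts as accepted:
  yes, either route suffices (configurable).
* Breathing segments do not overlap (as for ECG); overlap is a
  `spectral_config`-style parameter only for STFT windows.
* The PSG breathing channel is processed per channel with thorax as
  default; channel fusion is out of scope.
* No significance test between feature-set AUCs is performed; DeLong
  CIs per curve are provided instead.
* EDF import/export is omitted (no EDF library in the supported
  dependency set); signals exchange as two-column CSV plus JSON sidecar.

# Limitations

Acceptance is property-based by necessity: the clinical cohort behind the
published headline numbers (AUCs near 0.98, repeatability medians near
78%) is unavailable, so those numbers cannot be recomputed and are not
claimed. The generator's artifact model is a stand-in calibrated only
qualitatively (sustained blocks, configurable fraction), and the
classifier's absolute performance on synthetic cohorts reflects the
generator's stated effect sizes, not clinical reality.
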