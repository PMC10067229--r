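---
title: "From continuous ECG to deterioration risk: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From continuous ECG to deterioration risk: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsishrv)
```

## The problem

Patients arriving at an emergency department (ED) with suspected early
sepsis may recover, remain stable, or deteriorate into progressive organ
dysfunction, ICU admission or death. Bedside risk scores (qSOFA and
similar) summarise vital signs at a single time point. Heart rate
variability (HRV) — the beat-to-beat variation of the cardiac interbeat
(NN) interval — can instead be computed continuously from the ECG the
bedside monitor already records, and depressed HRV is a classic signature
of autonomic dysregulation in critical illness.

`sepsishrv` implements the complete chain needed to test this idea on
continuous single-lead ECG: QRS detection, artifact-corrected NN
tachograms, windowed HRV features, admission-aligned 3-hour summaries,
organ-dysfunction stratification, and a screened, stepwise logistic model
for deterioration compared against bedside scores by AUROC. Because
monitor data of this kind are protected health data, the package ships a
synthetic-cohort generator with the same statistical structure, so every
stage is testable end to end.

## Pipeline overview

1. **R-peak detection** (`detect_r_peaks`). Canonical Pan-Tompkins stages:
   5–15 Hz Butterworth band-pass (applied zero-phase with `filtfilt`, so no
   group-delay correction is needed), five-point derivative, squaring, and a
   150 ms *centred* moving-window integration. Dual adaptive thresholds are
   maintained on both the integrated and the band-passed signal; detection
   requires both, with a 200 ms refractory period, a T-wave veto within
   360 ms, replacement of a refractory-window acceptance by a larger
   following peak, and search-back at halved thresholds when a beat is
   overdue (no peak within 1.66 times the running RR average). Accepted
   peaks are refined to the local maximum of the band-passed signal and
   interpolated parabolically to sub-sample precision. All parameters are
   exposed; the defaults are the classic 1985 values.

2. **NN intervals and artifact exclusion** (`compute_nn_intervals`,
   `correct_artifacts`). Interval *i* is the gap between peaks *i* and
   *i+1* in ms, stamped at the closing peak. Artifacts are flagged from the
   absolute difference of adjacent RR intervals (ADARRI): each interval is
   compared against the last *retained* interval, and flagged when the jump
   exceeds `max(median + k*MAD, floor)` computed on the record's own
   adjacent-difference distribution (defaults `k = 5`, `floor = 200` ms).
   The sequential reference prevents the clean interval that follows an
   ectopic short/long pair from being flagged as a third artifact. The MAD
   (50% breakdown) rather than a quantile spread keeps the scale estimate
   honest even when a short record carries many artifacts. The defaults
   follow a tail argument: for approximately Gaussian successive
   differences the ADARRI distribution is half-normal, and median + 5 MAD
   sits beyond the 1e-5 tail, while genuine ectopic or missed-beat jumps
   are of order half the mean NN interval (several hundred ms), far above
   both terms. Flagged intervals are **excluded**, never interpolated —
   interpolation fabricates data and biases spectral estimates.

3. **Windows** (`segment_windows`). Consecutive half-open 5-minute windows
   aligned to ED admission; an interval belongs to the window containing
   its end-time, so each interval is counted exactly once. A window is
   retained iff it holds at least 60 unflagged intervals — 20% of the 300
   beats minimally expected in five minutes — and a 48-hour record yields
   exactly 576 candidate windows.

4. **Features** (`feature_vector`). Seventeen per-window features:

   * time domain: AVNN, SDNN (n−1 denominator), RMSSD, NN50 (strictly
     greater than 50 ms — the conventional definition), pNN50, CV;
   * nonlinear: SampEn (m = 2, tolerance r = 0.2·SDNN of the window,
     Chebyshev distance, self-matches excluded) and the Poincaré axes
     SD1 = SDSD/√2, SD2 = √(2·SDNN² − SD1²);
   * frequency domain: ULF (< 0.003 Hz), VLF (0.0033–0.04), LF
     (0.04–0.15), HF (0.15–0.4) band powers in ms², TotalPower, LFnorm,
     HFnorm, LF/HF.

   Band powers integrate a Lomb-Scargle periodogram of the unevenly timed
   tachogram (the natural estimator for point-process data; a
   cubic-resample + FFT route, `welch_psd`, is provided as an independent
   cross-check). The grid is oversampled fourfold (Δf = 1/1200 Hz up to
   0.4 Hz) and powers are scaled so a sinusoidal modulation of amplitude A
   contributes ≈ A²/2 ms² to its band. **TotalPower is defined as LF + HF**
   — the definition used in the analysis this package operationalises —
   and the conventional full-band integral is additionally reported as
   `FullBandPower` to avoid ambiguity. LFnorm and HFnorm normalise by
   LF + HF, consistent with that TotalPower definition. A 5-minute window
   resolves nothing below 1/300 Hz ≈ 0.0033 Hz, so ULF (and marginally
   VLF) cannot truly be estimated there; both are still computed, to
   mirror the windowed design, but carry `ULF_unresolved`/`VLF_unresolved`
   flags. The 0.003–0.0033 Hz sliver between the printed ULF and VLF edges
   belongs to neither band. Missing components (e.g. SampEn with no
   template matches, norms when LF + HF = 0) propagate as `NA`, never as
   zero.

5. **Aggregation** (`summarize_bins`, `first_interval_matrix`). Features
   are summarised per 3-hour bin aligned to admission (16 bins over 48 h)
   as the arithmetic mean over non-missing windows and the OLS slope
   against the window *midpoint* time in hours (midpoints are the
   unambiguous centring choice; the mean needs ≥ 1 window, the slope ≥ 2).
   Modelling uses the bin-0 (first three hours) feature means — the
   information available while the patient is still in the ED. Slopes can
   be added via `include_slopes`, but are off by default since the
   modelled feature set is conventionally the plain means.

6. **Stratification** (`classify_outcome`). Daily assessments of three
   organ systems: AKI (creatinine rise ≥ 25.6 µmol/L above the earliest
   baseline at/before admission, or ≥ 150% of baseline; the printed 25.6
   is kept verbatim, with `use_canonical_kdigo` switching to 26.5); liver
   dysfunction (bilirubin > 35.2 µmol/L AND any of ALP/ASAT/ALAT > 2× the
   upper limit of normal); respiratory dysfunction (ventilation, PaO2
   < 8 kPa, PaCO2 > 6.5 kPa, SpO2 < 90% on ambient air, or SpO2 < 95% on
   ≥ 2 L/min oxygen), using the worst value per day. **POD** = a de novo
   organ system (not dysfunctional at the admission-day assessment)
   becoming dysfunctional within the horizon, or ICU admission or death
   within 72 h; **SOD** = dysfunction on admission day without any POD
   trigger; **NOD** = neither. Worsening *within* an already-dysfunctional
   organ system does not constitute progression — the rule requires a new
   organ system, the reading most faithful to "de novo". The organ horizon
   defaults to the same 72 h as the ICU/death triggers and is
   configurable.

7. **Statistics** (`kruskal_wallis_screen`, `univariate_logistic`,
   `forward_stepwise_aic`, `roc_auc`, `delong_compare`). Per feature ×
   summary-kind × bin, a Kruskal-Wallis rank test across NOD/SOD/POD with
   significance at p < 0.05, deliberately uncorrected for multiplicity
   (mirroring the screening design; a Benjamini-Hochberg adjustment can be
   applied to the returned p-values if desired). Prediction of POD
   (SOD and NOD pooled as controls) uses one univariate logistic fit per
   bin-0 feature with Wald 95% CIs on the OR scale; features with
   p < 0.20 enter a forward-stepwise search that adds the largest-AIC-drop
   candidate until no addition lowers AIC, with exact ties broken by
   candidate order (deterministic, no randomness). Separated or
   non-converged fits are flagged and excluded from candidacy. Model
   diagnostics report deviance (−2 log L), non-intercept degrees of
   freedom, and McFadden pseudo-R² (Nagelkerke optional). AUROC uses the
   Mann-Whitney formulation with ties counted ½; correlated AUROCs are
   compared with DeLong's structural-components test. qSOFA is computed
   from its Sepsis-3 components; any external severity score enters as a
   supplied column and is never reimplemented.

## The synthetic cohort: what it emulates

`simulate_cohort()` produces, per patient, an NN tachogram (optionally a
rendered 500 Hz ECG), a daily clinical course, comparator-score inputs and
a censoring time.

**Tachogram.** Beat times follow an integral-pulse-frequency-modulation
scheme: the instantaneous interval is `mean_nn` plus one sinusoid per
spectral band (band-limited noise optional), floored at 250 ms. Defaults:
mean NN 600 ms (≈100 bpm, septic tachycardia at triage), amplitudes
ULF/VLF/LF/HF = 30/25/15/10 ms (overall SDNN ≈ 30 ms — reduced HRV, as
expected in sepsis), centre frequencies 0.002/0.01/0.1/0.25 Hz. Ectopic
beats (default 1% of beats) displace a beat 40% of an interval early —
one shortened then one compensatory lengthened interval; missed beats
(0.5%) merge two intervals. These are exactly the two artifact classes the
ADARRI rule targets, and the generator records the corrupted indices as
ground truth.

**Group effects.** The published trajectories show lower AVNN and lower
ULF/VLF/total power in deteriorating patients, but print no effect sizes,
so the injected magnitudes are free design parameters chosen once: POD
multiplies mean NN by 0.85 and all band amplitudes by 0.5; SOD by 0.96 and
0.85. Between-patient variability is lognormal with sd 0.10 on the mean-NN
multiplier and 0.40 on the amplitude multiplier — HRV power varies far
more across individuals than resting heart rate, and with a smaller
amplitude spread the groups separate perfectly, which no clinical cohort
does. Note a structural consequence: because the effect is a multiplier on
mean and amplitudes, *every scale-carrying feature* inherits the injected
signal (SDNN, RMSSD, band powers, SampEn through the modulation-to-
tolerance ratio, …); only the ratio features LFnorm/HFnorm/LFHFratio
cancel it. Tests of "signal recovery" therefore count any scale-carrying
feature, while flag-rate checks focus on the four headline features
(AVNN, ULF, VLF, TotalPower).

**Clinical courses.** Courses are constructed so the stratification
criteria deterministically return the intended label, with safe margins on
either side of every threshold: NOD stays normal throughout; SOD carries
one randomly chosen dysfunction from day 0 with no further trigger; POD
realises exactly one of five triggers (de novo AKI/liver/respiratory
dysfunction with onset day 1–3, ICU admission at 4–70 h, or death at
12–70 h). qSOFA components and the external severity score are
group-conditional Gaussians (e.g. respiratory rate 20/23/26 ± 3 breaths
per minute, systolic BP 129/118/108 ± 12 mmHg for NOD/SOD/POD) chosen to
give comparator AUROCs in the 0.65–0.85 range typical of bedside scores.

**Attrition.** Censoring times are drawn from four segments (1–12 h,
12–24 h, 24–48 h, exactly 48 h) with probabilities 63:36:44:25 out of 168,
so the expected number of patients still monitored at 0/12/24/48 h matches
the 168/105/69/25 attrition profile of the study population; a 1-hour
floor guarantees every patient contributes first-bin windows.

**What it does not emulate.** Real EASI-lead morphology, respiration or
blood-pressure coupling, non-stationary circadian trends, beat-morphology
differences of ectopic beats, or electrode-motion artifact bursts. Passing
the pipeline's tests on this generator demonstrates algorithmic
correctness and recoverability of injected effects — not clinical
performance on hospital data.

## Numerical choices and degenerate inputs

* Beat generation, the threshold scan, SampEn counting and the
  Lomb-Scargle periodogram are in C++ (Rcpp); the periodogram uses a
  per-point recurrence across the uniform frequency grid, cross-checked in
  the tests against a literal R transcription of the formula.
* All-constant ECG → empty peak series with a warning; < 2 peaks → empty
  NN series; a window with < 2 intervals yields missing features.
* A constant NN series flags nothing (threshold floor), has SDNN = 0 and
  SampEn 0 (all templates match), and zero band powers with missing norms.
* Stepwise AIC stops at improvements smaller than 1e-10 to keep the
  stopping rule deterministic under floating-point noise; ties break by
  candidate order.
* Kruskal-Wallis on fully tied data is reported as H = 0, p = 1 (the
  tie-corrected statistic is 0/0 there; no evidence of group differences).
* Sample standard deviations use n−1 throughout.

## Problem sizes used by the tests

The test-suite and the acceptance script exercise the pipeline at sizes
chosen to make every property measurable while keeping a full run
comfortably reproducible on a single CPU: detection on three 1-hour
records spanning 50–140 bpm at 10 dB signal-power SNR; artifact flagging
on ≥ 10,000 intervals with 5% corruption; feature oracles on 1,000 random
windows; calibration nulls at 1,000 replicates (500 for CI coverage); and
50 seeded cohort replicates (168 patients, 119/38/11 group sizes) at the
NN-series level with 1-hour records — the modelled quantity is the bin-0
feature mean, for which the first hour already supplies twelve windows —
plus one full waveform-level run (rendered ECG, 15 min per patient)
through detection, correction, features, stratification and modelling.
Held-out AUROC uses stratified half-splits with the stepwise model refit
on the training half.

## Known limitations

* ULF/VLF from 5-minute windows are leakage-dominated (flagged, see
  above); interpret their group differences as differences in very-slow
  modulation amplitude, not calibrated band power.
* Exclusion (rather than interpolation) of flagged intervals slightly
  depletes beats in artifact-dense windows, which is then caught by the
  60-beat retention rule — the two rules are designed to interact.
* The stepwise-AIC + p < 0.20 screen is a variable-selection heuristic;
  its selections on correlated HRV features are unstable in small event
  counts (the POD group is small by design), which is visible in the
  replicate-to-replicate variation of the selected sets.
* qSOFA's GCS component cannot come from a monitor; the comparator inputs
  are single admission-time values by design.
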