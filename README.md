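# sepsishrv

Continuous-ECG heart rate variability (HRV) analysis for predicting
clinical deterioration in early sepsis at the emergency department (ED).

Patients presenting with suspected sepsis are monitored continuously for
up to 48 hours. This package implements the full analysis chain from the
raw 500 Hz single-lead ECG to a deterioration-risk model:

1. **R-peak detection** — a Pan-Tompkins detector (5–15 Hz band-pass,
   derivative, squaring, 150 ms moving-window integration, dual adaptive
   thresholds with refractory period and search-back), refined to
   sub-sample precision.
2. **NN-interval tachogram with artifact exclusion** — intervals whose
   absolute difference from the last retained interval (ADARRI) exceeds a
   robust record-specific threshold are flagged and excluded.
3. **Windowed HRV features** — 17 features per 5-minute window: AVNN,
   SDNN, RMSSD, NN50, pNN50, CV, SampEn, Poincaré SD1/SD2, and
   Lomb-Scargle band powers ULF (<0.003 Hz), VLF (0.0033–0.04), LF
   (0.04–0.15), HF (0.15–0.4), TotalPower (= LF + HF), LFnorm, HFnorm,
   LF/HF.
4. **3-hour summaries** — per-bin mean and OLS slope of each feature,
   aligned to ED admission (16 bins over 48 h).
5. **Outcome stratification** — no / stable / progressive organ
   dysfunction (NOD/SOD/POD) from daily creatinine, bilirubin and liver
   enzymes, blood gases, oxygenation and ventilation, plus ICU admission
   or death within 72 h.
6. **Statistics** — Kruskal-Wallis screening of each feature × bin across
   groups; univariate logistic fits of the first-3-hours feature means for
   POD (p < 0.20 gate); forward-stepwise-AIC multivariate logistic model;
   AUROC via the Mann-Whitney formulation and DeLong's test against
   comparator scores (qSOFA, external severity score).

A synthetic-cohort generator (`simulate_cohort`) produces IPFM-based
tachograms with per-band modulation, rendered ECG waveforms, clinical-lab
courses that classify deterministically into the intended group, and a
dropout process shaped like the study attrition — so the whole pipeline is
testable without any protected health data.

## Worked example

```r
library(sepsishrv)

# a synthetic cohort of 168 patients (119 NOD / 38 SOD / 11 POD),
# 3-hour records analysed at the NN-series level
cfg <- pipeline_config(sim = list(record_duration = 3 * 3600), seed = 11)
bundle <- run_pipeline(cfg)

table(bundle$labels$label)
#> NOD POD SOD
#> 119  11  38

bundle$model
#> Forward-stepwise-AIC logistic model
#>   selected: ULF, AVNN
#>   AIC 41.75 on n = 168

round(c(hrv = bundle$roc$auc_hrv, qsofa = bundle$roc$auc_qsofa,
        severity = bundle$roc$auc_severity), 3)
#>      hrv    qsofa severity
#>    0.964    0.750    0.895

subset(bundle$kw, bin_index == 0 & feature %in% c("AVNN", "ULF", "VLF"),
       c(feature, p_value, significant))
#>    feature      p_value significant
#>       AVNN 4.127910e-06        TRUE
#>        ULF 5.304819e-07        TRUE
#>        VLF 1.367779e-06        TRUE
```

The run above was produced with the shipped defaults (output values from
an actual run at seed 11 with 3-hour records): the stepwise model selects
the ultra-low-frequency power and the mean NN interval — the two features
whose group effects the generator injects most strongly — and the
Kruskal-Wallis screen flags them in the first 3-hour bin. The in-sample
AUROC of 0.96 reflects the deliberately strong synthetic effect sizes,
not expected clinical performance.

Individual stages are exported too: `detect_r_peaks()`,
`correct_artifacts()`, `segment_windows()`, `feature_vector()`,
`summarize_bins()`, `classify_outcome()`, `forward_stepwise_aic()`,
`roc_auc()`, `delong_compare()`. A thin command-line dispatcher with
`simulate` / `preprocess` / `features` / `aggregate` / `stratify` /
`analyze` / `run` subcommands is installed at `inst/cli/hrvpipe.R`.

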