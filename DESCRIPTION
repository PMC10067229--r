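Package: sepsishrv
Title: Heart Rate Variability Pipeline for Predicting Deterioration in Early Sepsis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end, testable pipeline from continuous single-lead ECG to
    a deterioration-risk model for patients with suspected early sepsis at the
    emergency department. Detects R peaks with a Pan-Tompkins detector, corrects
    RR-interval artifacts with an ADARRI-style rule, computes time-domain,
    Poincare, sample-entropy and Lomb-Scargle spectral heart rate variability
    features over 5-minute windows, summarises them as 3-hour means and slopes
    aligned to admission, stratifies patients into no / stable / progressive
    organ dysfunction from daily clinical criteria, and screens and models
    features with Kruskal-Wallis tests and forward-stepwise-AIC logistic
    regression, comparing the model to bedside scores by AUROC with DeLong's
    test. A synthetic-cohort generator produces ECG waveforms, ground-truth
    tachograms and clinical courses so every stage is testable without
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml,
    rlang,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
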