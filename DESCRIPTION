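Package: prvstress
Title: Ultra-Short-Term Stress-Index Estimation from Pulse Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for studying how accurately the Baevsky Stress Index,
    computed from one minute of photoplethysmography (PPG), can be predicted
    from shorter feature-acquisition windows (5-60 s). Includes a synthetic
    PPG/NN-interval cohort generator emulating rest and post-exercise states,
    PPG preprocessing (trimming, band-pass filtering, peak detection, z-score
    outlier replacement), the 18 standard time-domain pulse rate variability
    features, the Baevsky Stress Index with a 50 ms interval histogram,
    sliding-window dataset construction with agreement-based feature selection,
    and a four-regressor 10-fold cross-validated evaluation grid.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    ranger,
    xgboost,
    caret,
    jsonlite,
    withr,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
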