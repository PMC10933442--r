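Package: arousalint
Title: Automated Scoring and Per-Stage Classification of Sleep Arousal Intensity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the intensity of cortical arousals in polysomnography
    recordings from the peak-to-peak EEG amplitude on the central channels,
    bins events into quantile-based intensity levels with sham (non-arousal)
    controls, extracts a 136-dimensional pre-arousal-normalised feature set
    (5-level Daubechies-4 discrete wavelet transform statistics plus spectral,
    power and detrended-fluctuation features), and trains one optimised
    multiclass classifier per sleep stage (SMOTE balancing, recursive feature
    elimination with cross-validation, tree-structured Parzen estimator
    tuning with successive-halving pruning). Includes a synthetic
    polysomnography generator with controllable arousal amplitude strata so
    the full pipeline can be exercised and validated without clinical data,
    a minimal EDF reader/writer, and per-class evaluation reports
    (sensitivity, specificity, PPV, NPV, one-vs-rest AUROC).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    ranger,
    xgboost,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
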