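Package: hrvFatigue
Title: Operational Fatigue Grading and Prediction from Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grading and predicting occupational fatigue during graded
    exercise from RR-interval recordings. Computes the ten standard heart-rate and
    heart-rate-variability features (mean RR, HR, SDNN, RMSSD, LF, HF, LF/HF,
    Poincare SD1, SD2, SD2/SD1), derives an entropy-weighted composite fatigue
    index from Borg RPE ratings and simple reaction times, grades fatigue by
    K-means clustering with silhouette-based model selection and consolidation
    into mild/moderate/severe bands, and fits a small 10-8-1 feedforward network
    mapping the HRV features to the composite index. Includes a protocol-faithful
    synthetic graded-treadmill cohort generator with known ground truth, so the
    whole pipeline is testable end to end without access to subject data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
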