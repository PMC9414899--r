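Package: SomnoStage
Title: Sleep-Stage Classification from Multimodal Wearable Sensor Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulation, preprocessing, feature extraction, modeling and
    evaluation for sleep staging from chest- and finger-worn sensor systems.
    Generates overnight multimodal recordings (ECG, triaxial acceleration,
    SpO2, proximal/distal skin temperature) with ground-truth hypnograms,
    synchronizes and filters the streams, detects R peaks with the
    Pan-Tompkins algorithm, computes 73 per-epoch features across
    accelerometer, heart-rate-variability, temperature and oximetry
    modalities, trains personal and population sleep-stage classifiers under
    nested cross-validation with class rebalancing, and reports pooled
    Cohen's kappa, per-class metrics and sleep-architecture summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    signal,
    ranger,
    xgboost,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
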