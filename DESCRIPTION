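Package: tremordx
Title: Discriminating Parkinson's Disease from Essential Tremor with
    Wrist Accelerometry and Polygenic Risk Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for at-home differential diagnosis of Parkinson's
    disease (PD) versus essential tremor (ET) from smart-watch
    accelerometer recordings and consumer-grade genotyping.
    Reconstructs gameplay recording sessions from raw triaxial
    accelerometer streams and tremor questionnaire logs, extracts
    3-7 Hz band-passed tremor features (total energy, average and
    maximum amplitude), computes a 22-SNP weighted polygenic risk
    score, fits per-session linear-probability classifiers with
    median-per-subject aggregation, and evaluates discrimination by
    ROC/AUC. Includes a synthetic cohort generator so the complete
    pipeline can be exercised and calibrated without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    jsonlite
Config/testthat/edition: 3
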