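Package: plsconn
Title: Partial Least Squares Linking Functional Connectomes to Psychopathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multivariate analysis of brain-behaviour covariance in developmental
    clinical cohorts. Builds Fisher-z ridge partial-correlation connectomes from
    parcellated resting-state time series, prepares symptom and diagnosis blocks
    (missingness filtering, k-nearest-neighbour imputation, confound
    residualization), fits rotated and non-rotated (contrast) behavioural partial
    least squares correlation with permutation significance and bootstrap-ratio
    edge stability, summarises edge-level results to network blocks and nodal
    strength, and assesses split-sample replication by cross-projection of
    latent-variable weights. Includes a synthetic cohort generator with planted
    latent brain-behaviour dimensions, comorbidity, confounds and missingness so
    the full pipeline is testable without restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
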