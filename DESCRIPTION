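Package: mlsm
Title: Multivariate Lesion-Symptom Mapping with Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts longitudinal post-stroke language outcomes from acute
    lesion anatomy. Binary lesion masks are smoothed, converted to per-region
    lesion load vectors against a labelled brain atlas, combined with
    demographic and clinical covariates, and used to predict bounded (0-10)
    language scores at multiple timepoints via leave-one-out cross-validated
    linear epsilon-insensitive support vector regression. Out-of-sample
    performance is scored with prediction r-squared and RMSE across nested
    model families, and model feature weights are thresholded and projected
    back into brain space. A seeded synthetic-cohort generator (atlas,
    contiguous lesions, covariates, longitudinal scores with missingness and
    dropout) carries known ground truth so the full pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
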