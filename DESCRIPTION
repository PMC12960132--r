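Package: facenorms
Title: Normative Growth-Curve References for 3D Facial Anthropometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds population-specific normative references for facial
    measurements derived from 3D landmark coordinates. Computes
    interlandmark distances, angles, depths and midsagittal asymmetries
    from landmark tables with placement quality control; fits sex-specific
    growth curves per measurement from five candidate families (exponential
    decay and polynomials of degree one to four) with residual-sum-of-squares
    or small-sample AIC selection, an iterative three-standard-deviation
    outlier reappraisal loop, kernel-smoothed age-varying standard deviations
    and bootstrap confidence bands; scores individual subjects by age- and
    sex-matched Z-scores with atypical-trait flagging beyond two standard
    deviations; and compares trait counts across reference populations.
    Includes a calibrated synthetic cohort generator so the whole pipeline
    can be exercised without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
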