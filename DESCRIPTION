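Package: tivagree
Title: Agreement, Harmonization and Longitudinal Reliability of Intracranial Volume Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing agreement between registration-based (eTIV)
    and segmentation-based (sbTIV) estimates of total intracranial volume in
    multi-site MRI studies. Implements two-way random-effects intraclass
    correlation coefficients (ICC(2,1) and ICC(2,k)) with qualitative
    reliability bands, traveling-subject harmonization of procedure-specific
    additive biases via mixed models, resampled cross-procedure reliability,
    deviation and absolute-error analytics with a small-eTIV failure split,
    and longitudinal method-comparison mixed models for adolescent and adult
    cohorts. A synthetic multi-site cohort generator, calibrated to published
    per-procedure summary statistics, makes every analysis exercisable
    without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    Matrix,
    splines,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
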