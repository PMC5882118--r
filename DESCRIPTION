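Package: sgusdx
Title: Salivary Gland Ultrasound Scoring and Integrated Classification for
    Sjogren's Syndrome
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements an ultrasound (US)-based grading system for the major
    salivary glands in Sjogren's syndrome (SS): per-gland logistic probability
    models over binary parenchymal findings (hypoechoic areas, hyperechoic
    bands, irregular borders), a 0-4 ordinal US grade derived from summed
    gland scores, ACR/EULAR classification-criteria item scoring, and an
    integrated ACR/EULAR + US score system. Provides model refitting from
    labeled gland data (univariate screening, multivariable logistic
    regression, Steel-Dwass all-pairs comparison of fitted probabilities),
    threshold-grid sweeps with sensitivity/specificity/accuracy, k-fold
    cross-validation with per-fold threshold selection, a synthetic-cohort
    generator emulating the statistical structure of SS study cohorts, CSV
    cohort input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
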