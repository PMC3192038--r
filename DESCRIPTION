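Package: mciprog
Title: Trajectory-Based Prognosis of MCI-to-AD Conversion from Structural MRI Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for prognosticating conversion from mild cognitive
    impairment (MCI) to Alzheimer's disease (AD) from structural MRI
    tissue-density features. Derives "converter-by-trajectory" labels for
    MCI subjects by scoring their longitudinal scans with an AD-vs-Control
    linear maximum-margin classifier, fitting a line to each subject's
    score trajectory, and checking whether it reaches the AD side of the
    decision boundary; then trains and evaluates a second baseline-scan
    classifier that predicts those labels. Includes margin-based feature
    elimination (MFE) and recursive feature elimination (RFE) wrappers with
    a validation-based stopping rule, atlas-region biomarker selection by
    retained-voxel fractions, point-biserial biomarker validation with the
    Meng-Rosenthal-Rubin correlated correlation test, and a seeded
    synthetic longitudinal cohort simulator with planted group effects,
    age confounds, CDR courses and missing visits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
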