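Package: lfsrisk
Title: Risk Prediction and Validation for Li-Fraumeni Syndrome Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Mendelian risk prediction for families segregating deleterious
    germline TP53 variants (Li-Fraumeni syndrome). Implements carrier-probability
    inference by exact pedigree peeling, cause-specific competing-risk penetrance
    under gamma frailty, recurrent-event (multiple-primary-cancer) penetrance via
    a nonhomogeneous Poisson process, Kaplan-Meier comparator penetrance, the
    Classic and Chompret clinical criteria, a synthetic family-cohort generator
    emulating research-protocol and clinical-counseling data collection (with
    structured missingness), likelihood-based parameter estimation, and a
    validation pipeline (ROC/AUC, observed/expected calibration, family
    bootstrap confidence intervals, cohort summary tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
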