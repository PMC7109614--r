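Package: copdflow
Title: Decision-Support Engine for Early Diagnosis of COPD in Primary Care
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An executable redesign of the primary-care diagnostic pathway for
    chronic obstructive pulmonary disease (COPD): opportunistic screening
    eligibility and questionnaire scoring, spirometry session validation
    (calibration, attempt quality, the 0.15 L reproducibility criterion) and
    airflow-obstruction classification against either the fixed 0.7 FEV1/FVC
    cut or a demographic lower limit of normal, BODE/BODEx severity and CAT
    impact staging with specialist-referral logic, a differential-diagnosis
    knowledge base with explainable feature matching, and a business-process
    state machine that executes the whole pathway with task-level traceability.
    A seeded synthetic-cohort generator with known obstruction ground truth
    makes every stage, and the end-to-end process, testable without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
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
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
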