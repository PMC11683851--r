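Package: pewsval
Title: External Validation of Paediatric Early Warning Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to externally validate point-based paediatric early
    warning and mortality-risk scores in stratified hospital cohorts.
    Provides declarative (YAML-driven) calculators for ten published
    scores (LODS, FASTER, TOPRS, ITAT, WHO emergency signs, Mpimbaza,
    Brighton PEWS, PEDIA early/late, RISC, RISC-Malawi), a
    population-weighted validation engine (weighted Mann-Whitney AUC
    with bootstrap confidence intervals, Youden-optimal cutoffs,
    confusion-matrix metrics, Mandrekar discrimination bands, stratified
    and fixed-horizon analyses), and a synthetic cohort generator that
    emulates a multi-site 2:1:2 nutritionally stratified enrolment
    design so the pipeline can be exercised without restricted patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
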