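Package: pcsvet
Title: Stability-Based Vetting of Rule-Based Clinical Decision Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to derive and vet interpretable rule-based clinical
    decision instruments (CDIs) before external validation, following the
    predictability-computability-stability (PCS) discipline. Includes a
    synthetic trauma-cohort generator with covariate and prevalence shift,
    the standard preprocessing screens (missingness, inter-rater kappa,
    median imputation, redundancy merging, stratified splitting), greedy
    Gini-based CART trees and one-sided rule lists, a simplified rule
    ensemble, the weighted sensitivity/specificity diagnostic battery,
    permutation-importance and refit stability analysis, and frozen-model
    external validation with rank-concordance reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
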