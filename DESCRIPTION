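Package: cyp3addi
Title: Genotype-Stratified CYP3A Inhibition Kinetics and PBPK Drug-Drug
    Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates reversible-inhibition (Ki, Dixon analysis) and
    time-dependent-inactivation (kobs, kinact, KI) kinetics of CYP3A4 and
    CYP3A5 from genotyped human-liver-microsome assay data, and feeds the
    fitted constants into a minimal physiologically-based pharmacokinetic
    (PBPK) model of a CYP3A-cleared victim drug (tacrolimus) to predict
    drug-drug-interaction AUC ratios in CYP3A5 expressers and
    non-expressers under single-dose and multidose perpetrator regimens.
    Includes synthetic-data generators for velocity grids, inactivation
    time courses and virtual observed blood profiles, plus scenario
    orchestration and report rendering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
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
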