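Package: coversamp
Title: Coverage Sampling for Chart-Review Cohorts in Computable Phenotype Development
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised selection of chart-review samples that cover a patient
    cohort. Clusters a cohort on clinical features, draws many stratified
    candidate samples with equal per-cluster allocation, and keeps the candidate
    minimizing the nth nearest neighbor coverage distance (the sum over all
    cohort members of the distance to their nth closest sampled member).
    Includes a clustered-cohort simulator with a logistic phenotype outcome
    model, probabilistic computable-phenotype fitting (plain and lasso logistic
    regression), AUROC evaluation overall and by subgroup with bootstrap
    confidence intervals, standardized mean difference balance diagnostics, and
    a benchmark harness comparing coverage sampling against random and
    truth-stratified baselines.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    MASS,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble
LinkingTo: Rcpp
Suggests:
    cluster,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
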