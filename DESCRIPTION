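Package: skinDRS
Title: Composite Disease Risk Scores and Lifetime Risk Trajectories for
    Skin Cancer Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates composite disease risk scores for the three
    major skin cancers (basal cell carcinoma, squamous cell carcinoma and
    melanoma) from case-control survey cohorts with genotype dosages. Covers
    the full analysis path: a per-variant logistic association scan with
    principal-component covariates, genomic-control diagnostics, clumping-and-
    thresholding polygenic risk scores and analytic association power; staged
    logistic-GLM risk-factor selection with polynomial age modelling, deviance
    decomposition, variance-inflation and interaction diagnostics; grouped
    risk scores, a global disease risk score (DRS) and its age-free companion
    (DRSA); percentile-bin tail-enrichment and age-of-diagnosis evaluation;
    and DRSA-stratified lifetime risk trajectories with prevalence-to-
    incidence conversion, survival-weighted expected ages of diagnosis and
    prospective follow-up validation. A synthetic cohort generator with a
    yearly-hazard disease mechanism provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Epidemiology, GenomeWideAssociationStudy, Regression, Survival
RoxygenNote: 7.3.3
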