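Package: dcvdrisk
Title: Liability-Threshold Risk Models for Cardiovascular Disease in Type 2 Diabetes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probit (liability-threshold) risk modelling for cardiovascular
    complications of type 2 diabetes. Builds genetic, nongenetic and
    multifactorial liability models from SNP weight tables (risk-allele
    frequency and per-allele odds ratio) and categorical covariate schemes,
    converts odds ratios to penetrances and liability-scale mean shifts,
    computes posterior and incidence-based lifetime risks with competing
    disease-free mortality, constructs log-odds polygenic risk scores with
    min-max normalization to a common 0-10 scale, and evaluates models by
    rank-based AUC with DeLong confidence intervals, per-point odds ratios,
    continuous net reclassification improvement, stratified 10-fold
    cross-validation and per-cohort analyses. Includes a synthetic cohort
    generator (Hardy-Weinberg genotypes, additive liability, threshold
    disease model, correlated family history, life-table fixtures) so the
    full pipeline is testable without restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
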