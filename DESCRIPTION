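Package: lipidprs
Title: Unweighted Lipid Polygenic Risk Scores and Coronary Disease Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds unweighted (allele-count) polygenic risk scores for LDL
    cholesterol, HDL cholesterol and triglycerides from a 13-SNP panel,
    including APOE epsilon-haplotype inference from rs429358/rs7412, and
    analyses their association with lipid levels, guideline lipid thresholds
    and coronary artery disease. Provides genotype quality control (call
    rate, risk-allele frequency, exact Hardy-Weinberg test), Friedewald and
    apolipoprotein-B-based LDL derivation, unit conversions and log-scale
    effect interpretation, linear and logistic association models with
    tertile/quartile contrasts, ROC-based comparison of nested risk models,
    and a synthetic-cohort generator that reproduces the statistical
    structure the analysis assumes so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
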