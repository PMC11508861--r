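# lipidprs

Unweighted lipid polygenic risk scores and their association with lipid
levels, guideline thresholds and coronary artery disease.

## What this package is for

Blood lipids — LDL cholesterol, HDL cholesterol and triglycerides (TG) —
are strongly heritable, and a handful of common variants capture a useful
slice of that heritability. In populations without population-specific
effect estimates (for example Afro-Caribbean cohorts, where published
European-ancestry weights do not transfer), the defensible genetic
summary is an **unweighted polygenic risk score**: for each subject,
simply count trait-raising alleles,

```
PRS = Σ_j d_j ,   d_j ∈ {0, 1, 2},
```

over a small curated SNP panel. `lipidprs` implements the full analysis
chain a lipid-genetics study needs around that score, for
epidemiologists and statistical geneticists working with cohorts of a
few hundred to a few thousand subjects:

* a bundled 13-SNP panel defining three scores — LDL-PRS (5 SNPs),
  HDL-PRS (4 HDL-*lowering* SNPs) and TG-PRS (5 SNPs plus the APOE ε2
  haplotype dosage);
* genotype QC: call rates, risk-allele frequencies, and an exact
  conditional Hardy–Weinberg test (probability-ordering two-sided rule)
  suited to near-monomorphic variants, with a Bonferroni-style family
  threshold (0.05/13 ≈ 3.85×10⁻³);
* APOE ε2/ε3/ε4 calling from unphased rs429358/rs7412 dosages under the
  no-ε1 assumption (the double heterozygote resolves to ε2/ε4, flagged);
* lipid handling: Friedewald LDL (`TC − HDL − TG/2.2`, refused at
  TG ≥ 3.9 mmol/L where an apoB-based estimate takes over), unit
  conversions (38.67 / 88.57 mg/dL per mmol/L), natural-log modelling of
  HDL/TG with per-allele percent interpretation `100(e^b − 1)`, and the
  six guideline threshold flags;
* association models: OLS of (log-)lipids on the continuous allele count
  (excluding CAD and lipid-medication subjects), logistic models of
  threshold flags and CAD with per-allele odds ratios, explained
  variability of PRS-only vs adjusted models, tertile/quartile
  contrasts with ties assigned to the lower bin;
* discrimination: DeLong AUC confidence intervals and the DeLong paired
  test for nested CAD models ({age, sex, PRS} vs {risk factors} vs
  {risk factors + PRS});
* a synthetic-cohort generator that reproduces the statistical structure
  the analyses assume (HWE genotypes at the panel frequencies, APOE at
  the haplotype level, lipid marginals 3.08 ± 0.89 / 1.36 ± 0.48 /
  1.11 ± 0.73 mmol/L, per-allele effects 0.144 / −0.021 / +0.018, a CAD
  liability model with per-allele OR 1.27 calibrated to 27.2%
  prevalence), so every stage runs and is testable without external
  data.

Everything is tidyverse-shaped: functions take a data frame first and
return tibbles, fitted objects have `tidy()`/`glance()` methods, and
result objects plot with `autoplot()`/`plot_bin_or()`.

## Worked example

```r
library(lipidprs)

sim    <- simulate_cohort(sim_config(), seed = 42)   # 705 subjects
cohort <- cohort_table(sim)                          # flags + thresholds + PRSs

qc_panel(sim$genotypes, cohort = cohort)[1:4, c(1, 5, 9, 10, 11)]
#>   rsid      call_rate   raf hwe_p pass
#> 1 rs12916       0.967 0.247 0.278 TRUE
#> 2 rs1529729     0.966 0.286 0.584 TRUE
#> 3 rs599839      0.963 0.219 0.514 TRUE
#> 4 rs429358      0.970 0.236 0.901 TRUE

fit_prs_linear(cohort, "LDL")
#> <prs_linear> LDL-PRS on ldl
#>   unadjusted beta 0.1409 (0.0651, 0.2167), p = 0.000308, r2 = 0.037
#>   adjusted   beta 0.1389 (0.0645, 0.2134), p = 0.000295, r2 = 0.092
#>   n = 350

fit_prs_logistic(cohort, "cad", "ldl_prs",
                 covariates = default_covariates("CAD"))
#> <prs_logistic> ldl_prs -> cad
#>   OR per allele 1.230 (1.073, 1.410), p = 0.00288, n = 705

compare_cad_models(cohort)
#> <cad_roc_comparison> n = 705
#>        model   auc conf.low conf.high n_cases n_controls p_vs_crf
#>  prs_age_sex 0.685    0.641     0.729     190        515       NA
#>          crf 0.727    0.685     0.768     190        515       NA
#>      crf_prs 0.736    0.695     0.776     190        515    0.165
```

Reading the output: the cohort was *generated* with a per-allele LDL
effect of 0.144 mmol/L and a per-allele CAD odds ratio of 1.27; the
fitted 0.141 mmol/L (95% CI 0.065–0.217) and OR 1.23 (1.07–1.41) recover
those inputs within sampling error at this cohort size. The linear model
excludes the 355 subjects with CAD and/or on lipid-lowering therapy
(n = 350 used); `r2` is the variance explained by the score alone (3.7%)
versus the fully adjusted model (9.2%). Adding the LDL-PRS to the
traditional-risk-factor CAD model moves the in-sample AUC from 0.727 to
0.736 (DeLong paired p = 0.165).

The whole pipeline (QC → APOE → scores → lipid derivation → association
tables → quartile ORs → ROC bundle, all as TSV plus a run log) runs with
one call, from files or from a simulation block:

```r
run_pipeline(list(simulate = list(n_subjects = 705), seed = 1), "results/")
```

or from the shell via the thin wrapper
`inst/scripts/lipidprs-pipeline.R` (`simulate` and `run-all`
subcommands).

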