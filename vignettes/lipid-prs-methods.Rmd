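---
title: "Unweighted lipid polygenic risk scores: models, simulation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unweighted lipid polygenic risk scores: models, simulation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidprs)
```

## The analysis this package implements

`lipidprs` implements a complete association pipeline for *unweighted*
polygenic risk scores (PRSs) of blood lipids. Three scores are built from a
13-SNP panel by plain allele counting: for each subject and each trait the
score is

$$\mathrm{PRS} = \sum_{j} d_j, \qquad d_j \in \{0, 1, 2\},$$

where $d_j$ is the number of trait-raising (for HDL: trait-*lowering*)
alleles carried at marker $j$. No per-variant weights are used: the panel
was assembled for a population in which published effect estimates are not
transferable, and an unweighted count is the defensible default when no
population-specific weights exist. The three default scores are:

* **LDL-PRS** (5 SNPs, maximum 10): rs12916 (*HMGCR*), rs1529729
  (*SMARCA4*), rs599839 (*SORT1*), rs429358 and rs7412 (*APOE*);
* **HDL-PRS** (4 SNPs, maximum 8): rs301 (*LPL*), rs3916027
  (*SLC18A1*/*LPL*), rs17231506 and rs708272 (*CETP*). These are
  HDL-*lowering* alleles, so the expected regression sign against HDL is
  negative;
* **TG-PRS** (5 SNPs + APOE ε2 dosage, maximum 12): rs1260326 (*GCKR*),
  rs17145713 (*BAZ1B*), rs3916027, rs328 (*LPL*), rs17108993 (*RBP4*),
  plus the number of APOE ε2 haplotypes as one additional 0/1/2 component.

The downstream chain is: genotype quality control → APOE ε calling → score
construction → lipid derivation and guideline categorisation → linear and
logistic association models → ROC comparison of nested coronary artery
disease (CAD) risk models. A synthetic-cohort generator with the same
statistical structure makes every stage runnable and testable without
access to individual-level data.

## APOE handling

rs429358 and rs7412 jointly define the ε haplotypes: ε4 = (rs429358-C,
rs7412-C), ε3 = (T, C), ε2 = (T, T). The fourth combination (C, T), ε1, is
vanishingly rare and is assumed absent. Under that assumption the ε2 count
is always `2 - dosage_C(rs7412)` — a fact the test suite checks
exhaustively over all nine unphased dosage combinations — and the
rs429358/rs7412 double heterozygote, which is genuinely ambiguous from
unphased data, is resolved to ε2/ε4 and flagged. Dosage pairs that would
require ε1 (more C alleles at rs429358 than at rs7412) cannot occur under
the assumption; when observed in real data they are called with as many ε4
copies as rs7412 allows and flagged `ambiguous`, so the caller is total and
never emits ε1.

Both APOE SNPs enter the LDL score as ordinary C-allele dosages; the TG
score uses the ε2 dosage as a single additive component. This means the two
APOE SNPs contribute one component (two underlying SNPs) to the TG score,
and reported "number of SNPs" for that score can be counted as five
markers + one haplotype or as seven SNPs depending on convention; the
package counts components (`n_markers = 6`).

## Genotype quality control

Per variant the QC report gives the call rate, genotype counts, risk-allele
frequency (RAF) and a Hardy–Weinberg equilibrium (HWE) p-value. Two
choices deserve comment:

* **Exact conditional HWE test.** Conditional on the sample size $n$ and
  the minor-allele count $n_a$, the heterozygote count $h$ has the exact
  distribution
  $$P(h) = \frac{n!\,2^h}{n_{AA}!\,h!\,n_{aa}!}\,
           \frac{n_A!\,n_a!}{(2n)!},$$
  and the two-sided p-value sums $P(h')$ over all $h'$ with
  $P(h') \le P(h_{\mathrm{obs}})$ (probability-ordering rule). The exact
  test is the default because several panel variants are near-monomorphic
  (RAF up to 0.94), where the χ² approximation is unreliable; the χ²
  version is available as an option. The implementation works in log
  space (stable for thousands of subjects); ties in the ordering rule are
  compared with a $1+10^{-9}$ relative guard so that mathematically equal
  probabilities computed in floating point are counted as ties, and the
  final sum is clamped to 1.
* **Thresholds.** A variant passes at call rate ≥ 0.95 and HWE
  $p > \alpha/m$ with $\alpha = 0.05$ over the $m = 13$ panel tests
  (Bonferroni-style family threshold, $3.85\times 10^{-3}$ at the
  defaults); both are configurable. RAFs and HWE are computed on CAD-free
  subjects by default — the convention for reporting population
  frequencies from a case–control sample — and this is configurable
  (`hwe_subset = "all"`).

## Lipid derivation and interpretation

LDL cholesterol, when not measured directly, is estimated by the
Friedewald equation in mmol/L, $\mathrm{LDL} = \mathrm{TC} - \mathrm{HDL} -
\mathrm{TG}/2.2$, *only* below TG = 3.9 mmol/L (340 mg/dL); at or above
that bound the function refuses and an apolipoprotein-B-based linear
estimate is used instead. The apoB calibration published for that purpose
is not bundled: the default constants (2.7 mmol/L per g/L apoB, zero
intercept) are an approximate physiologic calibration chosen by this
package and are pluggable — substantive use at high TG should supply
published coefficients. Subjects with high TG and no apoB keep a missing
LDL and are counted in the log.

Unit conversions use 38.67 mg/dL per mmol/L for cholesterol-class analytes
and 88.57 for triglycerides. These constants reproduce the conventional
printed mmol↔mg/dL pairs for every quantity handled here to within
rounding (the 2.6 mmol/L ↔ 100 mg/dL guideline pair is itself rounded on
both sides and converts back to 100.5).

HDL and TG are right-skewed and are log-transformed (natural log) before
linear modelling. On that scale a per-allele coefficient $b$ means a
$100(e^{b}-1)\%$ multiplicative change per allele, e.g. $b = -0.021$ is a
2.1% decrease; natural rather than base-10 logarithms are pinned by this
percent interpretation.

## Association models

Lipid-level models are ordinary least squares of the (possibly logged)
lipid on the PRS as a continuous allele count, excluding subjects on
lipid-lowering therapy and/or with CAD; threshold models are logistic
regressions of the six guideline flags (LDL > 2.6 and > 3.0 mmol/L,
HDL < 1.03 and > 1.55, TG > 1.69 and > 2.26) under the same exclusion;
CAD models are logistic regressions on the whole cohort. Default
adjustment sets are sex, age, BMI, diabetes plus smoking (LDL), alcohol
(HDL), alcohol and hypertension (TG), and age, sex, hypertension,
diabetes, smoking (CAD). All intervals are Wald 95% CIs (symmetric on the
log-odds scale before exponentiation); "explained variability" reports
the $r^2$ of the PRS-only model and of the fully adjusted model
separately. Each model is complete-case on its own columns and reports
`n_used`, the filter count and the NA-drop count.

Tertile/quartile contrasts cut the discrete score distribution at its
empirical quantiles with a tied value assigned wholly to the *lower* bin.
On heavily tied integer scores this produces deliberately unequal bin
shares (a "top quartile" can hold far less than 25% of subjects), which
is the honest behaviour for allele counts; tertile contrasts drop the
middle bin and compare top against bottom, quartile contrasts return one
OR per upper quartile against the lowest.

Missing genotypes and scores: the default scoring policy is mean
imputation (a missing dosage is replaced by twice the cohort RAF), so
model sample sizes match the full cohort at the ~97% call rates the
generator emulates; `complete_case` is available and every imputed score
is flagged `complete = FALSE`. Mean imputation is Berkson-like (the
imputed value is the conditional mean), so regression slopes on the score
are not attenuated the way classical measurement error would suggest;
the recovery tests confirm this empirically.

## Discrimination

AUCs are Mann–Whitney (ties counted half) with DeLong confidence
intervals, computed through pROC with a fixed direction so that an
anti-discriminating score shows an AUC below 0.5 instead of being flipped.
Nested CAD models — {age, sex, PRS}, {risk factors}, {risk factors + PRS}
— are fitted in-sample (no cross-validation, matching the descriptive
purpose) and the nested pair is compared with DeLong's paired test, the
standard test for correlated ROC curves; a bootstrap alternative exists in
pROC but is not wired in. Identical prediction vectors have a degenerate
paired variance; that case reports $p = 1$ with a flag rather than NaN.

## The synthetic-cohort generator

The generator's defaults *are* the study conditions the analyses assume;
they are not tuning knobs. Specifically:

* **Genotypes**: 705 subjects; 11 non-APOE variants as independent HWE
  binomials at the panel's Afro-Caribbean RAFs; APOE drawn at the
  *haplotype* level with (ε2, ε3, ε4) = (0.09, 0.67, 0.24) and converted
  to the two SNP dosages. Haplotype-level simulation is essential: it
  induces the positive dependence between the rs429358 and rs7412 dosages
  (no ε1) that contributes covariance to the LDL-PRS variance; without it
  the analytic variance below would be wrong. Optional haplotype
  correlation for the two CETP SNPs; 3% missingness per variant (call
  rate ≈ 97%).
* **Lipids**: LDL $= 3.08 + 0.144\,(\mathrm{PRS} - E[\mathrm{PRS}])$ plus
  modest centred age/BMI terms and a Gaussian residual whose SD is solved
  so the marginal SD is exactly 0.89 mmol/L; log-HDL and log-TG likewise
  on the natural-log scale with per-allele effects −0.021 and +0.018 and
  marginal mean/SD 1.36/0.48 and 1.11/0.73 mmol/L via the lognormal
  moment relations. The generator errors if configured effects exceed the
  target marginal variance. TC is composed as LDL + HDL + TG/2.2 plus
  noise (SD 0.02), so the Friedewald estimate approximately recovers the
  generated LDL. TG is capped below 3.9 mmol/L by default so the
  Friedewald branch applies uniformly (high-TG subjects are rare in the
  emulated population); a flag disables the cap and emits apoB for
  exercising the high-TG branch. The cap slightly attenuates the
  realised TG slope (≈ 0.0172 rather than 0.018 at scale).
* **Covariates**: age 53.71 (SD 14.02) years truncated at 18; male 49.4%;
  BMI 27.06 (SD 5.46); hypertension 40.6%, diabetes 17.3%, smoking 19.7%,
  regular alcohol 18.5%, lipid-lowering therapy 26.2%. Blood pressure and
  medication fields are drawn *consistently* with the hypertension flag so
  that re-deriving clinical flags from raw fields reproduces the drawn
  prevalence. Covariate effects on lipids are package choices (zero for
  HDL/TG; small age/BMI terms on LDL so the adjusted model explains more
  variance than the score alone); no published values exist for them and
  no acceptance quantity depends on them.
* **CAD**: a logistic liability with per-allele odds ratio 1.27 on the
  LDL-PRS and modest coefficients on age, sex, hypertension, diabetes and
  smoking; the intercept is solved numerically (uniroot on the mean
  fitted probability over the realised linear predictor, bracket ±30,
  tolerance $10^{-4}$) so the marginal prevalence hits the 27.2% target.

With these defaults the expected PRS-only LDL $r^2$ has a closed form:
$\beta^2 \mathrm{Var(PRS)}/0.89^2$ with
$\mathrm{Var(PRS)} = \sum 2p(1-p)$ over the three non-APOE LDL SNPs plus
the APOE block variance
$2[\,e_4(1-e_4) + e_2(1-e_2) + 2e_2e_4\,] = 0.615$, i.e.
$\mathrm{Var} \approx 1.746$ and $r^2 \approx 4.6\%$. The test suite
checks the empirical $r^2$ against this closed form at $n = 10^5$.

**What the generator does not emulate**: population admixture,
relatedness, genotyping batch effects, sex-specific TG distributions,
treatment effects of lipid-lowering therapy, or per-SNP effect
heterogeneity (effects are homogeneous per allele on the summed score, the
structure the unweighted count assumes). Passing recovery tests therefore
demonstrate that the *estimators* are correct under the assumed model, not
that the model captures every feature of real cohort data.

## Numerical and reproducibility choices

* Every stochastic entry point takes a mandatory integer seed; identical
  seeds give byte-identical cohorts and reports.
* Replicate loops never seed consecutive integers. R's Mersenne-Twister
  states initialised from nearby seeds are correlated in their early
  output, and we measured material bias in across-replicate averages from
  consecutive seeding; `replicate_seeds()` draws per-replicate seeds from
  a single master stream and is used by every replicated computation in
  the package, its tests and its acceptance script.
* Problem sizes in the tests are chosen to keep the default suite fast
  while leaving Monte-Carlo error well inside each assertion's tolerance:
  large-n checks use $10^5$ subjects, recovery and calibration checks use
  200 replicates of cohorts of 473–705 subjects, and assertion bounds are
  set at ≥3 Monte-Carlo standard errors.
* Logistic fits that separate (fitted probabilities pinned at 0/1 or
  non-convergence) are flagged and report `NA` estimates instead of
  numerically meaningless coefficients.
* A constant outcome reports $r^2 = 0$ (nothing to explain) rather than
  the indeterminate ratio `summary.lm` produces when both model and
  residual sums of squares vanish.

## Known limitations

* The apoB-based LDL constants are an approximate placeholder calibration
  (documented above); the Martin–Hopkins and Sampson LDL equations are out
  of scope.
* No weighted PRS is implemented (weights would require
  population-specific effect estimates); the scoring layer is the place a
  weighting hook would live.
* No per-subject QC (relatedness, heterozygosity), no imputation from
  reference panels, no liftover; VCF ingestion matches panel variants by
  rsid in the ID field only.
* No multiple-testing correction is applied across the association tables
  (each cell is reported with its own p-value), and CAD discrimination is
  in-sample.
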