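#' Simulation configuration for synthetic cohorts
#'
#' Bundles every generating parameter of the synthetic-cohort model. The
#' defaults reproduce the descriptive structure of the Afro-Caribbean
#' study population the package's analyses assume: genotypes at the
#' panel's Afro-Caribbean risk-allele frequencies under Hardy-Weinberg
#' equilibrium, APOE drawn at the haplotype level with
#' (eps2, eps3, eps4) = (0.09, 0.67, 0.24), per-allele lipid effects of
#' 0.144 mmol/L (LDL), -0.021 (log-HDL) and +0.018 (log-TG), marginal
#' lipid means/SDs of 3.08/0.89 (LDL), 1.36/0.48 (HDL) and 1.11/0.73
#' mmol/L (TG), covariate prevalences (hypertension 40.6%, diabetes
#' 17.3%, smoking 19.7%, regular alcohol 18.5%, lipid-lowering therapy
#' 26.2%, male 49.4%), age 53.71 (SD 14.02) years, a CAD liability model
#' with per-allele odds ratio 1.27 on the LDL score calibrated to 27.2%
#' prevalence, and 3% genotype missingness per variant (call rate ~97%).
#'
#' @param n_subjects Cohort size (default 705; lipid-level models in the
#'   source design use the 473 CAD-free, untreated subjects).
#' @param panel Variant panel with generating `raf_ac` frequencies.
#' @param score_defs Score definitions used to build the generating PRSs.
#' @param apoe_freqs Named numeric `(e2, e3, e4)` haplotype frequencies
#'   (must sum to 1).
#' @param beta_ldl,beta_loghdl,beta_logtg Generating per-allele effects
#'   (mmol/L for LDL; natural-log scale for HDL and TG).
#' @param ldl_mean,ldl_sd,hdl_mean,hdl_sd,tg_mean,tg_sd Marginal lipid
#'   means and SDs (mmol/L); residual SDs are derived from these so the
#'   marginal targets hold by construction.
#' @param age_mean,age_sd,bmi_mean,bmi_sd,p_male Covariate marginals.
#' @param p_hypertension,p_diabetes,p_smoking,p_alcohol,p_lipid_lowering
#'   Binary covariate prevalences.
#' @param beta_ldl_age,beta_ldl_bmi Modest covariate effects on LDL
#'   (mmol/L per year / per kg/m2, centered), so the adjusted model
#'   captures more variance than the PRS alone.
#' @param cad_prevalence Target marginal CAD prevalence.
#' @param cad_log_or Named log-odds coefficients of the CAD liability
#'   model: `prs` (per LDL-PRS allele), `age` (per year, centered),
#'   `male`, `hypertension`, `diabetes`, `smoking`.
#' @param missing_rate Per-variant genotype missingness.
#' @param cetp_ld_r Haplotype correlation between the two CETP SNPs
#'   (rs17231506/rs708272); 0 = independent.
#' @param tc_noise_sd SD of the noise added to the composed total
#'   cholesterol (`ldl + hdl + tg/2.2`).
#' @param cap_tg Cap simulated TG below 3.9 mmol/L (default `TRUE`), so
#'   the Friedewald branch applies to the whole cohort.
#' @param simulate_high_tg When `TRUE`, disables the TG cap and emits an
#'   `apob` column so the apoB-based LDL branch can be exercised.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects = 705,
                       panel = ac_panel(),
                       score_defs = default_score_definitions(),
                       apoe_freqs = c(e2 = 0.09, e3 = 0.67, e4 = 0.24),
                       beta_ldl = 0.144, beta_loghdl = -0.021, beta_logtg = 0.018,
                       ldl_mean = 3.08, ldl_sd = 0.89,
                       hdl_mean = 1.36, hdl_sd = 0.48,
                       tg_mean = 1.11, tg_sd = 0.73,
                       age_mean = 53.71, age_sd = 14.02,
                       bmi_mean = 27.06, bmi_sd = 5.46,
                       p_male = 0.494,
                       p_hypertension = 0.406, p_diabetes = 0.173,
                       p_smoking = 0.197, p_alcohol = 0.185,
                       p_lipid_lowering = 0.262,
                       beta_ldl_age = 0.008, beta_ldl_bmi = 0.015,
                       cad_prevalence = 0.272,
                       cad_log_or = c(prs = log(1.27), age = 0.05, male = 0.75,
                                      hypertension = 0.7, diabetes = 0.5,
                                      smoking = 0.6),
                       missing_rate = 0.03,
                       cetp_ld_r = 0,
                       tc_noise_sd = 0.02,
                       cap_tg = TRUE,
                       simulate_high_tg = FALSE) {
  if (n_subjects < 1) abort("n_subjects must be at least 1")
  if (abs(sum(apoe_freqs) - 1) > 1e-8) abort("apoe haplotype frequencies must sum to 1")
  if (any(apoe_freqs < 0)) abort("apoe haplotype frequencies must be non-negative")
  if (any(panel$raf_ac < 0 | panel$raf_ac > 1)) abort("generating RAFs must lie in [0, 1]")
  stopifnot(ldl_sd > 0, hdl_sd > 0, tg_sd > 0, age_sd > 0, bmi_sd > 0,
            missing_rate >= 0, missing_rate < 1,
            cad_prevalence > 0, cad_prevalence < 1,
            abs(cetp_ld_r) <= 1)
  cfg <- list(
    n_subjects = as.integer(n_subjects), panel = panel, score_defs = score_defs,
    apoe_freqs = apoe_freqs,
    beta_ldl = beta_ldl, beta_loghdl = beta_loghdl, beta_logtg = beta_logtg,
    ldl_mean = ldl_mean, ldl_sd = ldl_sd, hdl_mean = hdl_mean, hdl_sd = hdl_sd,
    tg_mean = tg_mean, tg_sd = tg_sd,
    age_mean = age_mean, age_sd = age_sd, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
    p_male = p_male, p_hypertension = p_hypertension, p_diabetes = p_diabetes,
    p_smoking = p_smoking, p_alcohol = p_alcohol,
    p_lipid_lowering = p_lipid_lowering,
    beta_ldl_age = beta_ldl_age, beta_ldl_bmi = beta_ldl_bmi,
    cad_prevalence = cad_prevalence, cad_log_or = cad_log_or,
    missing_rate = missing_rate, cetp_ld_r = cetp_ld_r,
    tc_noise_sd = tc_noise_sd, cap_tg = cap_tg,
    simulate_high_tg = simulate_high_tg
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Analytic moments of a generating PRS
#'
#' Expectation and variance of an allele-count PRS implied by the
#' generating frequencies: independent Hardy-Weinberg binomials for
#' non-APOE members (`2p` and `2p(1-p)` each), the APOE block at the
#' haplotype level (which makes the rs429358 and rs7412 dosages in the
#' LDL score positively dependent), optional CETP haplotype correlation,
#' and the eps2 dosage for the TG score.
#'
#' @param cfg A [sim_config()].
#' @param trait `"LDL"`, `"HDL"` or `"TG"`.
#' @return A list with `mean` and `var`.
#' @export
prs_moments <- function(cfg, trait) {
  def <- cfg$score_defs[cfg$score_defs$trait == trait, ]
  if (nrow(def) != 1) abort(paste0("no score definition for trait ", trait))
  members <- def$members[[1]]
  e2 <- cfg$apoe_freqs[["e2"]]; e4 <- cfg$apoe_freqs[["e4"]]
  apoe_snps <- intersect(members, c("rs429358", "rs7412"))
  plain <- setdiff(members, apoe_snps)
  p <- cfg$panel$raf_ac[match(plain, cfg$panel$rsid)]
  m <- 2 * sum(p)
  v <- 2 * sum(p * (1 - p))
  # CETP pair: per-haplotype allele correlation adds 2 * 2 * cov_hap
  cetp <- intersect(plain, c("rs17231506", "rs708272"))
  if (length(cetp) == 2 && cfg$cetp_ld_r != 0) {
    p1 <- cfg$panel$raf_ac[cfg$panel$rsid == "rs17231506"]
    p2 <- cfg$panel$raf_ac[cfg$panel$rsid == "rs708272"]
    cov_hap <- cfg$cetp_ld_r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
    v <- v + 2 * 2 * cov_hap
  }
  if (length(apoe_snps) == 2) {
    # d429358 counts eps4 haplotypes; d7412 counts non-eps2 haplotypes
    var_a <- e4 * (1 - e4)
    var_b <- e2 * (1 - e2)
    cov_ab <- e4 * e2           # Cov(1[eps4], 1[!eps2]) = e4 - e4(1 - e2)
    m <- m + 2 * e4 + 2 * (1 - e2)
    v <- v + 2 * (var_a + var_b + 2 * cov_ab)
  } else if (length(apoe_snps) == 1) {
    pa <- if (apoe_snps == "rs429358") e4 else 1 - e2
    m <- m + 2 * pa
    v <- v + 2 * pa * (1 - pa)
  }
  if (isTRUE(def$include_apoe_e2)) {
    m <- m + 2 * e2
    v <- v + 2 * e2 * (1 - e2)
  }
  list(mean = m, var = v)
}

#' Simulate panel genotypes
#'
#' Draws risk-allele dosages for every panel variant: non-APOE variants
#' as independent Hardy-Weinberg binomials at their generating
#' frequencies; the two APOE SNPs jointly, by sampling two epsilon
#' haplotypes per subject and converting them to rs429358/rs7412 C
#' dosages (inducing the natural cross-SNP dependence and excluding
#' eps1); and, optionally, the two CETP SNPs from correlated haplotypes.
#' Missing calls are then inserted independently at the configured rate.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (required; every stochastic entry point in
#'   the package takes one).
#' @return A genotype tibble (`subject_id` + one dosage column per
#'   variant).
#' @export
simulate_genotypes <- function(cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  simulate_genotypes_impl(cfg)
}

simulate_genotypes_impl <- function(cfg) {
  n <- cfg$n_subjects
  geno <- tibble(subject_id = sprintf("S%04d", seq_len(n)))
  apoe <- sample_apoe_haplotypes(n, cfg$apoe_freqs)
  plain <- setdiff(cfg$panel$rsid, c("rs429358", "rs7412"))
  cetp <- c("rs17231506", "rs708272")
  use_ld <- cfg$cetp_ld_r != 0 && all(cetp %in% plain)
  for (rs in plain) {
    if (use_ld && rs %in% cetp) next
    p <- cfg$panel$raf_ac[cfg$panel$rsid == rs]
    geno[[rs]] <- rbinom(n, 2, p)
  }
  if (use_ld) {
    p1 <- cfg$panel$raf_ac[cfg$panel$rsid == cetp[1]]
    p2 <- cfg$panel$raf_ac[cfg$panel$rsid == cetp[2]]
    pair <- sample_correlated_pair(n, p1, p2, cfg$cetp_ld_r)
    geno[[cetp[1]]] <- pair[, 1]
    geno[[cetp[2]]] <- pair[, 2]
  }
  geno$rs429358 <- apoe$d429358_c
  geno$rs7412 <- apoe$d7412_c
  geno <- geno[, c("subject_id", cfg$panel$rsid)]
  if (cfg$missing_rate > 0) geno <- apply_missingness(geno, cfg$missing_rate)
  geno
}

# Two epsilon haplotypes per subject -> C dosages at the two APOE SNPs.
sample_apoe_haplotypes <- function(n, freqs) {
  haps <- matrix(sample(c("e2", "e3", "e4"), 2 * n, replace = TRUE,
                        prob = freqs[c("e2", "e3", "e4")]), ncol = 2)
  d429358 <- rowSums(haps == "e4")
  d7412 <- rowSums(haps != "e2")
  tibble(d429358_c = as.integer(d429358), d7412_c = as.integer(d7412),
         e2 = as.integer(rowSums(haps == "e2")))
}

# Dosage pair at two biallelic SNPs from 2n correlated haplotypes.
sample_correlated_pair <- function(n, p1, p2, r) {
  cov_hap <- r * sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  p11 <- p1 * p2 + cov_hap
  if (p11 < max(0, p1 + p2 - 1) || p11 > min(p1, p2)) {
    abort("cetp_ld_r implies an invalid haplotype frequency")
  }
  draw_hap <- function() {
    u <- runif(n)
    a <- integer(n); b <- integer(n)
    cuts <- cumsum(c(p11, p1 - p11, p2 - p11))
    a <- as.integer(u < cuts[1] | (u >= cuts[1] & u < cuts[2]))
    b <- as.integer(u < cuts[1] | (u >= cuts[2] & u < cuts[3]))
    cbind(a, b)
  }
  draw_hap() + draw_hap()
}

apply_missingness <- function(geno, rate) {
  for (rs in setdiff(names(geno), "subject_id")) {
    drop <- runif(nrow(geno)) < rate
    geno[[rs]][drop] <- NA_integer_
  }
  geno
}

#' Simulate phenotypes and lipid levels for a genotype table
#'
#' Draws covariates at their configured marginals and generates lipids
#' from the generating PRSs (computed on the supplied, ideally complete,
#' genotypes): LDL is Gaussian around `ldl_mean` with the per-allele
#' effect applied to the centered LDL-PRS and modest centered age/BMI
#' effects; log-HDL and log-TG are Gaussian on the natural-log scale
#' with the log-scale mean/SD derived from the target marginal mean/SD
#' via the lognormal relation. Residual SDs are solved so the marginal
#' SDs equal their targets; the call errors if the configured effects
#' already exceed the target variance. Total cholesterol is composed as
#' `ldl + hdl + tg/2.2` plus small noise, so the Friedewald estimate
#' approximately recovers the generated LDL. Blood-pressure readings and
#' medication flags are drawn consistently with the hypertension
#' prevalence, so [derive_clinical_flags()] reproduces the drawn flags.
#'
#' @param geno Genotype tibble without missing calls (the generating
#'   truth); missing dosages error.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A phenotype tibble in the [read_phenotypes()] layout (plus a
#'   measured `ldl` column), with the generating PRSs in attribute
#'   `"prs"`.
#' @export
simulate_lipids <- function(geno, cfg, seed) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  simulate_lipids_impl(geno, cfg)
}

simulate_lipids_impl <- function(geno, cfg) {
  if (anyNA(geno[setdiff(names(geno), "subject_id")])) {
    abort("simulate_lipids needs complete genotypes (the generating truth)")
  }
  n <- nrow(geno)
  scores <- compute_prs(geno, cfg$score_defs, missing_policy = "complete_case")
  prs <- scores %>%
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "trait",
                       values_from = "score")
  prs <- prs[match(geno$subject_id, prs$subject_id), ]

  age <- pmax(18, rnorm(n, cfg$age_mean, cfg$age_sd))
  male <- runif(n) < cfg$p_male
  bmi <- pmax(15, rnorm(n, cfg$bmi_mean, cfg$bmi_sd))
  hyp <- runif(n) < cfg$p_hypertension
  diab <- runif(n) < cfg$p_diabetes
  smoke <- runif(n) < cfg$p_smoking
  alco <- runif(n) < cfg$p_alcohol
  lipmed <- runif(n) < cfg$p_lipid_lowering

  # BP and antihypertensive use drawn so flag derivation reproduces `hyp`
  on_aht <- hyp & runif(n) < 0.7
  sbp <- ifelse(hyp & !on_aht, pmax(140, rnorm(n, 150, 8)),
         ifelse(hyp, rnorm(n, 142, 12), pmin(139, rnorm(n, 124, 9))))
  dbp <- ifelse(hyp & !on_aht, rnorm(n, 92, 6),
         ifelse(hyp, rnorm(n, 86, 8), pmin(89, rnorm(n, 76, 7))))

  mom_ldl <- prs_moments(cfg, "LDL")
  var_cov <- cfg$beta_ldl_age^2 * cfg$age_sd^2 + cfg$beta_ldl_bmi^2 * cfg$bmi_sd^2
  res_var_ldl <- cfg$ldl_sd^2 - cfg$beta_ldl^2 * mom_ldl$var - var_cov
  if (res_var_ldl <= 0) abort("LDL effects exceed the target marginal variance")
  ldl <- cfg$ldl_mean + cfg$beta_ldl * (prs$LDL - mom_ldl$mean) +
    cfg$beta_ldl_age * (age - cfg$age_mean) +
    cfg$beta_ldl_bmi * (bmi - cfg$bmi_mean) +
    rnorm(n, 0, sqrt(res_var_ldl))
  ldl <- pmax(ldl, 0)

  hdl <- simulate_lognormal_lipid(prs$HDL, prs_moments(cfg, "HDL"),
                                  cfg$beta_loghdl, cfg$hdl_mean, cfg$hdl_sd, n)
  tg <- simulate_lognormal_lipid(prs$TG, prs_moments(cfg, "TG"),
                                 cfg$beta_logtg, cfg$tg_mean, cfg$tg_sd, n)
  if (cfg$cap_tg && !cfg$simulate_high_tg) tg <- pmin(tg, 3.89)

  tc <- pmax(ldl + hdl + tg / 2.2 + rnorm(n, 0, cfg$tc_noise_sd), 0)
  apob <- if (cfg$simulate_high_tg) pmax(0.2, ldl / 2.7 + rnorm(n, 0, 0.05)) else NA_real_

  pheno <- tibble(
    subject_id = geno$subject_id,
    age = age, sex = factor(ifelse(male, "male", "female"),
                            levels = c("male", "female")),
    bmi = bmi, sbp = sbp, dbp = dbp,
    tc = tc, hdl = hdl, tg = tg, ldl = ldl, apob = apob,
    on_antihypertensive = on_aht, on_lipid_lowering = lipmed,
    diabetes_history = diab, smoker_current = smoke, alcohol_regular = alco,
    cad = NA
  )
  attr(pheno, "prs") <- prs
  pheno
}

# Lognormal marginal matched to (mean, sd) with a per-allele log-scale shift.
simulate_lognormal_lipid <- function(score, mom, beta, target_mean, target_sd, n) {
  sigma2 <- log(1 + (target_sd / target_mean)^2)
  mu <- log(target_mean) - sigma2 / 2
  res_var <- sigma2 - beta^2 * mom$var
  if (res_var <= 0) abort("log-scale effect exceeds the target marginal variance")
  exp(mu + beta * (score - mom$mean) + rnorm(n, 0, sqrt(res_var)))
}

#' Simulate CAD labels from a logistic liability model
#'
#' `logit P(CAD) = alpha + b_prs * LDL-PRS + b_age * (age - mean) +
#' b_male * male + b_hyp * hypertension + b_diab * diabetes +
#' b_smoke * smoking`, where `alpha` is solved numerically so the
#' marginal prevalence over the supplied subjects matches the configured
#' target (within 0.002 in expectation).
#'
#' @param pheno Phenotype tibble from [simulate_lipids()] (its `"prs"`
#'   attribute supplies the generating LDL-PRS; pass `prs_ldl` to
#'   override).
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param prs_ldl Optional numeric vector of LDL-PRS values.
#' @return `pheno` with the `cad` column filled; the solved intercept is
#'   stored in attribute `"cad_alpha"`.
#' @export
simulate_cad <- function(pheno, cfg, seed, prs_ldl = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  simulate_cad_impl(pheno, cfg, prs_ldl)
}

simulate_cad_impl <- function(pheno, cfg, prs_ldl = NULL) {
  if (is.null(prs_ldl)) {
    prs <- attr(pheno, "prs")
    if (is.null(prs)) abort("pheno lacks a 'prs' attribute; pass prs_ldl explicitly")
    prs_ldl <- prs$LDL
  }
  b <- cfg$cad_log_or
  eta <- b[["prs"]] * prs_ldl +
    b[["age"]] * (pheno$age - cfg$age_mean) +
    b[["male"]] * (pheno$sex == "male") +
    b[["hypertension"]] * derive_clinical_flags(pheno)$hypertension +
    b[["diabetes"]] * pheno$diabetes_history +
    b[["smoking"]] * pheno$smoker_current
  alpha <- solve_liability_intercept(eta, cfg$cad_prevalence)
  p <- plogis(alpha + eta)
  pheno$cad <- runif(length(p)) < p
  attr(pheno, "cad_alpha") <- alpha
  attr(pheno, "prs") <- attr(pheno, "prs")
  pheno
}

# Intercept of the liability model hitting the target mean probability.
solve_liability_intercept <- function(eta, target, tol = 1e-4) {
  f <- function(a) mean(plogis(a + eta)) - target
  sol <- tryCatch(uniroot(f, interval = c(-30, 30), tol = tol),
                  error = function(e) abort("target prevalence unreachable given coefficients"))
  sol$root
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_genotypes()], [simulate_lipids()] and [simulate_cad()]
#' under one seed and returns genotypes (with missingness), the true
#' (complete) genotypes, phenotypes with CAD labels, and a
#' generating-truth record sufficient to rerun parameter-recovery
#' checks.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A `synthetic_cohort` list: `genotypes` (observed, with
#'   missingness), `genotypes_true`, `phenotypes`, `truth`.
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 100), seed = 42)
#' names(sim)
#' @export
simulate_cohort <- function(cfg = sim_config(), seed) {
  stopifnot(inherits(cfg, "sim_config"))
  if (missing(seed)) abort("a seed is required")
  set.seed(seed)
  saved <- cfg$missing_rate
  cfg$missing_rate <- 0
  geno_true <- simulate_genotypes_impl(cfg)
  cfg$missing_rate <- saved
  pheno <- simulate_lipids_impl(geno_true, cfg)
  pheno <- simulate_cad_impl(pheno, cfg)
  geno_obs <- if (saved > 0) apply_missingness(geno_true, saved) else geno_true
  truth <- list(
    seed = seed, n_subjects = cfg$n_subjects,
    beta_ldl = cfg$beta_ldl, beta_loghdl = cfg$beta_loghdl,
    beta_logtg = cfg$beta_logtg,
    cad_or_per_allele = exp(cfg$cad_log_or[["prs"]]),
    cad_alpha = attr(pheno, "cad_alpha"),
    cad_prevalence_target = cfg$cad_prevalence,
    prs_moments = list(LDL = prs_moments(cfg, "LDL"),
                       HDL = prs_moments(cfg, "HDL"),
                       TG = prs_moments(cfg, "TG")),
    raf = setNames(cfg$panel$raf_ac, cfg$panel$rsid),
    apoe_freqs = cfg$apoe_freqs
  )
  structure(list(genotypes = geno_obs, genotypes_true = geno_true,
                 phenotypes = pheno, truth = truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> n =", nrow(x$phenotypes),
      "| variants =", ncol(x$genotypes) - 1,
      "| CAD prevalence =", round(mean(x$phenotypes$cad), 3), "\n")
  invisible(x)
}

#' Analysis-ready cohort table from a synthetic cohort
#'
#' Convenience assembly mirroring the real-data pipeline: derives
#' clinical flags and threshold categories, and attaches the three PRS
#' columns computed from the *observed* genotypes (mean-imputed by
#' default, so sample sizes match the full cohort).
#'
#' @param sim A `synthetic_cohort` from [simulate_cohort()].
#' @param missing_policy Passed to [add_prs()].
#' @return A cohort tibble ready for the association and discrimination
#'   functions.
#' @export
cohort_table <- function(sim, missing_policy = "mean_impute") {
  stopifnot(inherits(sim, "synthetic_cohort"))
  sim$phenotypes %>%
    derive_clinical_flags() %>%
    categorize_lipids() %>%
    add_prs(sim$genotypes, sim$config$score_defs, missing_policy = missing_policy)
}

#' Derive independent replicate seeds from a master seed
#'
#' Draws `n` distinct seeds from the stream initialised by `seed`.
#' Replicated simulations must not be seeded with consecutive integers:
#' Mersenne-Twister states initialised from nearby seeds are correlated
#' in their early output, which measurably biases Monte-Carlo averages
#' across replicates. All replicate loops in this package (and its
#' acceptance harness) draw their per-replicate seeds this way.
#'
#' @param seed Master integer seed.
#' @param n Number of replicate seeds.
#' @return An integer vector of `n` seeds, deterministic given `seed`.
#' @export
replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Parameter-recovery report over replicated synthetic cohorts
#'
#' Simulates `n_replicates` cohorts, refits the generating associations
#' on each (unadjusted linear models for the three lipid effects; the
#' fully adjusted logistic model for the CAD per-allele odds ratio), and
#' summarises, per generating parameter: the mean estimate, bias, and
#' empirical coverage of the 95% Wald interval. Deterministic given the
#' seed.
#'
#' @param cfg A [sim_config()].
#' @param n_replicates Number of replicate cohorts (>= 1).
#' @param seed Integer seed.
#' @return A tibble with one row per parameter: `parameter`, `truth`,
#'   `mean_estimate`, `bias`, `coverage`, `n_replicates`.
#' @export
recovery_report <- function(cfg = sim_config(), n_replicates = 200, seed = 1) {
  if (n_replicates < 1) abort("n_replicates must be at least 1")
  seeds <- replicate_seeds(seed, n_replicates)
  rows <- purrr::map(seeds, function(s) {
    sim <- simulate_cohort(cfg, seed = s)
    cohort <- cohort_table(sim)
    est <- purrr::map(c("LDL", "HDL", "TG"), function(tr) {
      g <- glance(fit_prs_linear(cohort, tr))
      tibble(parameter = paste0("beta_", switch(tr, LDL = "ldl", HDL = "loghdl",
                                                TG = "logtg")),
             estimate = g$beta_unadjusted,
             low = g$conf.low_unadjusted, high = g$conf.high_unadjusted)
    }) %>% bind_rows()
    gc <- glance(fit_prs_logistic(cohort, "cad", "ldl_prs",
                                  covariates = default_covariates("CAD")))
    bind_rows(est, tibble(parameter = "cad_or_per_allele",
                          estimate = gc$or_per_allele,
                          low = gc$conf.low, high = gc$conf.high))
  }) %>% bind_rows()
  truths <- c(beta_ldl = cfg$beta_ldl, beta_loghdl = cfg$beta_loghdl,
              beta_logtg = cfg$beta_logtg,
              cad_or_per_allele = exp(cfg$cad_log_or[["prs"]]))
  rows %>%
    mutate(truth = unname(truths[.data$parameter])) %>%
    group_by(.data$parameter) %>%
    summarise(
      truth = .data$truth[1],
      mean_estimate = mean(.data$estimate),
      bias = mean(.data$estimate) - .data$truth[1],
      coverage = mean(.data$low <= .data$truth & .data$truth <= .data$high),
      n_replicates = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(match(.data$parameter, names(truths)))
}
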