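test_that("simulated allele frequencies match their generating values", {
  cfg <- sim_config(n_subjects = 1e5, missing_rate = 0)
  g <- simulate_genotypes(cfg, seed = 501)
  raf <- risk_allele_frequency(g)
  for (i in seq_len(nrow(raf))) {
    p <- cfg$panel$raf_ac[cfg$panel$rsid == raf$rsid[i]]
    se <- sqrt(p * (1 - p) / (2 * raf$n_used[i]))
    expect_lt(abs(raf$raf[i] - p), 3 * se + 1e-9)
  }
  # rs7412 C frequency follows from the epsilon2 haplotype frequency
  expect_equal(raf$raf[raf$rsid == "rs7412"], 1 - cfg$apoe_freqs[["e2"]],
               tolerance = 0.01)
})

test_that("the APOE block induces the no-epsilon1 dosage dependence", {
  g <- simulate_genotypes(sim_config(n_subjects = 2e4, missing_rate = 0), seed = 502)
  # rs429358 C dosage can never exceed rs7412 C dosage without epsilon1
  expect_true(all(g$rs429358 <= g$rs7412))
  calls <- apoe_from_genotypes(g)
  freq_e2 <- sum(calls$e2) / (2 * nrow(g))
  expect_lt(abs(freq_e2 - 0.09), 0.005)  # ~3.5 binomial SEs at 4e4 haplotypes
})

test_that("missingness control: zero rate gives full call rates", {
  g0 <- simulate_genotypes(sim_config(n_subjects = 500, missing_rate = 0), seed = 503)
  expect_true(all(call_rate(g0)$call_rate == 1))
  g3 <- simulate_genotypes(sim_config(n_subjects = 5000, missing_rate = 0.03), seed = 503)
  expect_true(all(abs(call_rate(g3)$call_rate - 0.97) < 0.02))
})

test_that("CETP linkage disequilibrium is honoured when requested", {
  cfg <- sim_config(n_subjects = 3e4, missing_rate = 0, cetp_ld_r = 0.6)
  g <- simulate_genotypes(cfg, seed = 504)
  r_obs <- cor(g$rs17231506, g$rs708272)
  expect_equal(r_obs, 0.6, tolerance = 0.05)
  expect_error(sim_config(cetp_ld_r = 1.5), "cetp_ld_r")
})

test_that("marginal lipid moments hit their targets at large n", {
  cfg <- sim_config(n_subjects = 1e5, missing_rate = 0)
  sim <- simulate_cohort(cfg, seed = 505)
  ph <- sim$phenotypes
  expect_lt(abs(mean(ph$ldl) - 3.08), 0.02)
  expect_lt(abs(sd(ph$ldl) / 0.89 - 1), 0.02)
  expect_lt(abs(mean(ph$hdl) - 1.36), 0.02)
  expect_lt(abs(sd(ph$hdl) / 0.48 - 1), 0.03)
  expect_lt(abs(mean(ph$tg) - 1.11), 0.02)
  # TG is capped below the Friedewald validity bound by default
  expect_true(all(ph$tg < 3.9))
  # total cholesterol composes the fractions, so Friedewald round-trips
  expect_lt(max(abs(ph$tc - (ph$ldl + ph$hdl + ph$tg / 2.2))), 0.15)
  expect_lt(abs(mean(ph$age) - 53.71), 0.25)
  expect_lt(abs(mean(ph$sex == "male") - 0.494), 0.01)
})

test_that("binary covariate prevalences and derived flags line up", {
  sim <- simulate_cohort(sim_config(n_subjects = 4e4), seed = 506)
  flags <- derive_clinical_flags(sim$phenotypes)
  expect_lt(abs(mean(flags$hypertension) - 0.406), 0.01)
  expect_lt(abs(mean(flags$diabetes) - 0.173), 0.01)
  expect_lt(abs(mean(flags$smoking) - 0.197), 0.01)
  expect_lt(abs(mean(sim$phenotypes$on_lipid_lowering) - 0.262), 0.01)
  expect_false(any(is.na(flags$hypertension)))
})

test_that("the PRS-lipid effect is generated at the configured slope", {
  cfg <- sim_config(n_subjects = 1e5, missing_rate = 0, cap_tg = FALSE)
  sim <- simulate_cohort(cfg, seed = 507)
  prs <- attr(sim$phenotypes, "prs")
  # bounds are ~3 standard errors of each slope at n = 1e5
  b_ldl <- coef(lm(sim$phenotypes$ldl ~ prs$LDL))[[2]]
  expect_lt(abs(b_ldl - 0.144), 0.007)
  b_hdl <- coef(lm(log(sim$phenotypes$hdl) ~ prs$HDL))[[2]]
  expect_lt(abs(b_hdl - (-0.021)), 0.003)
  b_tg <- coef(lm(log(sim$phenotypes$tg) ~ prs$TG))[[2]]
  expect_lt(abs(b_tg - 0.018), 0.003)
})

test_that("zero effects give lipids independent of the score", {
  cfg <- sim_config(n_subjects = 473, beta_ldl = 0, beta_loghdl = 0, beta_logtg = 0)
  seeds <- replicate_seeds(508, 20)
  covered <- vapply(seeds, function(s) {
    cohort <- cohort_table(simulate_cohort(cfg, seed = s))
    g <- glance(fit_prs_linear(cohort, "LDL"))
    g$conf.low_unadjusted < 0 && 0 < g$conf.high_unadjusted
  }, logical(1))
  expect_gte(mean(covered), 0.9)
})

test_that("empirical PRS-only r-squared matches the analytic expectation", {
  cfg <- sim_config(n_subjects = 1e5, missing_rate = 0)
  mom <- prs_moments(cfg, "LDL")
  expected_r2 <- cfg$beta_ldl^2 * mom$var / cfg$ldl_sd^2
  sim <- simulate_cohort(cfg, seed = 509)
  prs <- attr(sim$phenotypes, "prs")
  r2 <- summary(lm(sim$phenotypes$ldl ~ prs$LDL))$r.squared
  expect_lt(abs(r2 / expected_r2 - 1), 0.05)
  # and the analytic variance matches the empirical score variance
  expect_lt(abs(var(prs$LDL) / mom$var - 1), 0.03)
})

test_that("CAD prevalence is calibrated to its target", {
  sim <- simulate_cohort(sim_config(n_subjects = 1e5), seed = 510)
  expect_lt(abs(mean(sim$phenotypes$cad) - 0.272), 0.01)
  # expected prevalence hits the target almost exactly at the solved intercept
  cfg0 <- sim_config(n_subjects = 2e4,
                     cad_log_or = c(prs = 0, age = 0, male = 0,
                                    hypertension = 0, diabetes = 0, smoking = 0))
  sim0 <- simulate_cohort(cfg0, seed = 511)
  expect_lt(abs(plogis(sim0$truth$cad_alpha) - 0.272), 1e-4)
  # with zero coefficients, labels are independent of the score
  prs <- attr(sim0$phenotypes, "prs")
  expect_lt(abs(cor(prs$LDL, sim0$phenotypes$cad)), 0.02)
})

test_that("simulation is fully deterministic under a fixed seed", {
  cfg <- sim_config(n_subjects = 300)
  a <- simulate_cohort(cfg, seed = 512)
  b <- simulate_cohort(cfg, seed = 512)
  expect_identical(a$genotypes, b$genotypes)
  expect_equal(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_cohort(cfg, seed = 513)
  expect_false(identical(a$genotypes, c_$genotypes))
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(n_subjects = 0), "at least 1")
  expect_error(sim_config(apoe_freqs = c(e2 = 0.5, e3 = 0.4, e4 = 0.3)), "sum to 1")
  expect_error(simulate_cohort(sim_config(n_subjects = 10)), "seed")
  # effects too large for the marginal variance
  expect_error(simulate_cohort(sim_config(n_subjects = 50, beta_ldl = 1.5), seed = 1),
               "exceed")
  expect_error(recovery_report(sim_config(), n_replicates = 0), "at least 1")
})

test_that("recovery report is reproducible and carries the truth", {
  cfg <- sim_config(n_subjects = 150)
  a <- recovery_report(cfg, n_replicates = 3, seed = 514)
  b <- recovery_report(cfg, n_replicates = 3, seed = 514)
  expect_identical(a, b)
  expect_setequal(a$parameter, c("beta_ldl", "beta_loghdl", "beta_logtg",
                                 "cad_or_per_allele"))
  expect_equal(a$truth[a$parameter == "beta_ldl"], 0.144)
  expect_true(all(a$n_replicates == 3))
})
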