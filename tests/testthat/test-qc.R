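test_that("call rate counts non-missing calls over all subjects", {
  g1 <- make_geno(list(rs12916 = c(1, 2, 0, 1, 0, 2, 1, 0, 2, 1)))
  expect_equal(call_rate(g1)$call_rate, 1.0)
  g2 <- make_geno(list(rs599839 = c(1, NA, 0, 2)))
  expect_equal(call_rate(g2)$call_rate, 0.75)
  g3 <- make_geno(list(rs301 = rep(NA_integer_, 4)))
  expect_equal(call_rate(g3)$call_rate, 0.0)
  expect_error(call_rate(g1, "rs_nope"), "unknown rsid")
})

test_that("risk allele frequency excludes missing calls from both sides", {
  expect_equal(risk_allele_frequency(make_geno(list(rs12916 = c(2, 1, 0))))$raf, 0.5)
  expect_equal(risk_allele_frequency(make_geno(list(rs12916 = c(2, 2, 2))))$raf, 1.0)
  g <- make_geno(list(rs12916 = c(1, NA, 0)))
  expect_equal(risk_allele_frequency(g)$raf, 0.25)  # 1 allele / (2 * 2 subjects)
  expect_equal(risk_allele_frequency(g)$n_used, 2)
  expect_error(risk_allele_frequency(g, subset = c(FALSE, TRUE, FALSE)),
               "no non-missing genotypes")
})

test_that("exact HWE test reproduces hand-enumerated small cases", {
  # n = 2 with 2 minor alleles: P(het = 2) = 2/3, P(het = 0) = 1/3
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # monomorphic: single outcome
  expect_equal(hwe_exact_test(7, 0, 0), 1.0)
  expect_equal(hwe_exact_test(0, 0, 12), 1.0)
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
  expect_error(hwe_exact_test(0, 0, 0), "at least one genotype")
})

test_that("exact HWE test equals the enumeration oracle for all triples with n <= 30", {
  for (n in 1:30) {
    for (a in 0:n) {
      for (h in 0:(n - a)) {
        c_ <- n - a - h
        expect_equal(hwe_exact_test(a, h, c_), hwe_oracle(a, h, c_),
                     tolerance = 1e-9,
                     info = sprintf("triple (%d, %d, %d)", a, h, c_))
      }
    }
  }
})

test_that("exact HWE test matches a permutation simulation", {
  # independent third route: shuffle 2n alleles into pairs
  sim_p <- function(n_rr, n_het, n_oo, reps = 40000) {
    n <- n_rr + n_het + n_oo
    alleles <- rep(c(1, 0), c(2 * n_rr + n_het, 2 * n_oo + n_het))
    obs <- hwe_exact_test(n_rr, n_het, n_oo)
    hets <- replicate(reps, {
      a <- sample(alleles)
      sum(a[seq(1, 2 * n, 2)] != a[seq(2, 2 * n, 2)])
    })
    probs <- table(hets) / reps
    p_obs <- probs[as.character(n_het)]
    sum(probs[probs <= p_obs * (1 + 1e-9)])
  }
  set.seed(42)
  expect_equal(hwe_exact_test(3, 4, 5), sim_p(3, 4, 5), tolerance = 0.02)
  expect_equal(hwe_exact_test(1, 9, 2), sim_p(1, 9, 2), tolerance = 0.02)
})

test_that("HWE test is valid: rejection rate at alpha stays at or below alpha", {
  set.seed(314)
  n <- 200
  p_values <- replicate(1200, {
    p <- runif(1, 0.1, 0.9)
    d <- rbinom(n, 2, p)
    hwe_exact_test(sum(d == 2), sum(d == 1), sum(d == 0))
  })
  # exact conditional test is conservative; allow MC error above alpha
  expect_lte(mean(p_values <= 0.05), 0.05 + 2.5 * sqrt(0.05 * 0.95 / 1200))
  expect_true(all(p_values > 0 & p_values <= 1))
})

test_that("chi-square variant agrees with the exact test at common frequencies", {
  set.seed(9)
  d <- rbinom(5000, 2, 0.4)
  counts <- c(sum(d == 2), sum(d == 1), sum(d == 0))
  p_exact <- hwe_exact_test(counts[1], counts[2], counts[3])
  p_chisq <- hwe_exact_test(counts[1], counts[2], counts[3], method = "chisq")
  expect_equal(p_exact, p_chisq, tolerance = 0.05)
})

test_that("qc_panel flags low call rate and computes the family threshold", {
  sim <- simulate_cohort(sim_config(n_subjects = 500, missing_rate = 0), seed = 21)
  rep <- qc_panel(sim$genotypes, cohort = sim$phenotypes)
  expect_equal(nrow(rep), 13)
  expect_equal(attr(rep, "hwe_threshold"), 0.05 / 13)
  expect_true(all(rep$call_rate == 1))
  expect_true(all(rep$pass))
  expect_true(all(abs(rep$raf - ac_panel()$raf_ac[match(rep$rsid, ac_panel()$rsid)]) < 0.08))

  # degrade one variant's call rate below the default 0.95 floor
  g <- sim$genotypes
  g$rs12916[1:50] <- NA
  rep2 <- qc_panel(g, cohort = sim$phenotypes)
  expect_false(rep2$pass[rep2$rsid == "rs12916"])
  expect_equal(rep2$call_rate[rep2$rsid == "rs12916"], 0.9)
})

test_that("qc_panel restricts RAF/HWE to CAD-free subjects by default", {
  sim <- simulate_cohort(sim_config(n_subjects = 600, missing_rate = 0), seed = 33)
  cad <- sim$phenotypes$cad
  rep_ctrl <- qc_panel(sim$genotypes, cohort = sim$phenotypes)
  rep_all <- qc_panel(sim$genotypes, cohort = sim$phenotypes, hwe_subset = "all")
  counts_ctrl <- rep_ctrl$n_hom_risk + rep_ctrl$n_het + rep_ctrl$n_hom_other
  expect_true(all(counts_ctrl == sum(!cad)))
  counts_all <- rep_all$n_hom_risk + rep_all$n_het + rep_all$n_hom_other
  expect_true(all(counts_all == length(cad)))
})
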