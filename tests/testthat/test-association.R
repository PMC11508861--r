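test_that("noiseless and degenerate linear fits behave exactly", {
  cohort <- small_cohort(n = 200, seed = 301, missing_rate = 0)
  # exact linear outcome: beta 2, r^2 1
  cohort$ldl <- 2 * cohort$ldl_prs
  g <- suppressWarnings(
    glance(fit_prs_linear(cohort, "LDL", covariates = character(0), exclude = FALSE))
  )
  expect_equal(g$beta_unadjusted, 2, tolerance = 1e-10)
  expect_equal(g$r_squared_unadjusted, 1, tolerance = 1e-10)
  # constant outcome: beta 0, r^2 0
  cohort$ldl <- 3.1
  g0 <- suppressWarnings(
    glance(fit_prs_linear(cohort, "LDL", covariates = character(0), exclude = FALSE))
  )
  expect_equal(g0$beta_unadjusted, 0, tolerance = 1e-12)
  expect_equal(g0$r_squared_unadjusted, 0)
})

test_that("single-predictor r-squared equals the squared Pearson correlation", {
  cohort <- small_cohort(n = 300, seed = 302)
  g <- glance(fit_prs_linear(cohort, "LDL"))
  keep <- !(cohort$cad %in% TRUE | cohort$on_lipid_lowering %in% TRUE)
  cc <- stats::complete.cases(cohort[keep, c("ldl", "ldl_prs", default_covariates("LDL"))])
  d <- cohort[keep, ][cc, ]
  expect_equal(g$r_squared_unadjusted, cor(d$ldl, d$ldl_prs)^2, tolerance = 1e-10)
})

test_that("adding covariates never decreases full-model r-squared", {
  cohort <- small_cohort(n = 350, seed = 303)
  for (tr in c("LDL", "HDL", "TG")) {
    g <- glance(fit_prs_linear(cohort, tr))
    expect_gte(g$r_squared_adjusted, g$r_squared_unadjusted - 1e-12)
  }
})

test_that("lipid-level models exclude CAD and lipid-medication subjects", {
  cohort <- small_cohort(n = 400, seed = 304)
  fit <- fit_prs_linear(cohort, "LDL")
  n_excluded <- sum(cohort$cad %in% TRUE | cohort$on_lipid_lowering %in% TRUE)
  expect_equal(fit$n_excluded_filter, n_excluded)
  expect_equal(fit$n_used + fit$n_dropped_na, nrow(cohort) - n_excluded)
  fit_all <- fit_prs_linear(cohort, "LDL", exclude = FALSE)
  expect_gt(fit_all$n_used, fit$n_used)
})

test_that("logistic OR with a binary exposure equals the 2x2 cross-product ratio", {
  # the printed-counts case: 20/80 exposed case/control, 10/90 unexposed
  make_tab_cohort <- function(a, b, c_, d) {
    tibble::tibble(
      subject_id = as.character(seq_len(a + b + c_ + d)),
      exposed = rep(c(1, 1, 0, 0), c(a, b, c_, d)),
      case = rep(c(TRUE, FALSE, TRUE, FALSE), c(a, b, c_, d)),
      cad = FALSE, on_lipid_lowering = FALSE
    )
  }
  g <- glance(fit_prs_logistic(make_tab_cohort(20, 80, 10, 90), "case", "exposed"))
  expect_equal(g$or_per_allele, (20 * 90) / (80 * 10), tolerance = 1e-6)
  # property over random all-positive tables
  set.seed(77)
  for (i in 1:25) {
    tab <- sample(5:60, 4, replace = TRUE)
    g <- glance(fit_prs_logistic(make_tab_cohort(tab[1], tab[2], tab[3], tab[4]),
                                 "case", "exposed"))
    expect_equal(g$or_per_allele, (tab[1] * tab[4]) / (tab[2] * tab[3]),
                 tolerance = 1e-6)
  }
})

test_that("null outcome gives OR near 1 with a covering CI", {
  set.seed(55)
  cohort <- small_cohort(n = 2000, seed = 305)
  cohort$noise_outcome <- runif(nrow(cohort)) < 0.3
  g <- glance(fit_prs_logistic(cohort, "noise_outcome", "ldl_prs", exclude = FALSE))
  expect_equal(g$or_per_allele, 1, tolerance = 0.15)
  expect_true(g$conf.low < 1 && 1 < g$conf.high)
})

test_that("complete separation is flagged with no estimate", {
  cohort <- tibble::tibble(
    subject_id = as.character(1:40),
    score = c(rnorm(20, 0), rnorm(20, 30)),
    sep_outcome = rep(c(FALSE, TRUE), each = 20),
    cad = FALSE, on_lipid_lowering = FALSE
  )
  fit <- fit_prs_logistic(cohort, "sep_outcome", "score")
  expect_true(fit$separation)
  expect_true(is.na(glance(fit)$or_per_allele))
  expect_error(fit_prs_logistic(dplyr::mutate(cohort, sep_outcome = TRUE),
                                "sep_outcome", "score"), "single class")
})

test_that("tertile contrast compares upper against lower bin only", {
  cohort <- small_cohort(n = 600, seed = 306)
  keep <- !is.na(cohort$ldl_prs)
  bins <- bin_score(tibble::tibble(subject_id = cohort$subject_id[keep],
                                   score = cohort$ldl_prs[keep]), k = 3)
  fit <- fit_bin_contrast(cohort, bins, "ldl_gt_3_0", covariates = c("age", "sex"))
  out <- tidy(fit)
  expect_equal(nrow(out), 1)
  expect_match(out$contrast, "bin3_vs_bin1")
  # strong positive generating effect: upper-tertile OR above 1
  expect_gt(out$or, 1)
})

test_that("quartile contrast returns exactly three ORs against Q1", {
  cohort <- small_cohort(n = 700, seed = 307)
  keep <- !is.na(cohort$ldl_prs)
  bins <- bin_score(tibble::tibble(subject_id = cohort$subject_id[keep],
                                   score = cohort$ldl_prs[keep]), k = 4)
  out <- tidy(fit_bin_contrast(cohort, bins, "cad",
                               covariates = default_covariates("CAD")))
  expect_equal(nrow(out), 3)
  expect_equal(out$contrast, c("bin2_vs_bin1", "bin3_vs_bin1", "bin4_vs_bin1"))
})

test_that("null-score quartile ORs cover 1 in most replicates", {
  seeds <- replicate_seeds(308, 20)
  cover <- vapply(seeds, function(s) {
    set.seed(s)
    n <- 300
    cohort <- tibble::tibble(
      subject_id = as.character(1:n),
      score = sample(0:10, n, replace = TRUE),
      y = runif(n) < 0.3,
      cad = FALSE, on_lipid_lowering = FALSE
    )
    bins <- bin_score(cohort[, c("subject_id", "score")], k = 4)
    out <- tidy(fit_bin_contrast(cohort, bins, "y"))
    all(out$or.conf.low < 1 & 1 < out$or.conf.high)
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("association tables have the expected shape", {
  cohort <- small_cohort(n = 500, seed = 309)
  lin <- association_table_linear(cohort)
  expect_equal(nrow(lin), 3)
  expect_true(all(c("beta_unadjusted", "r_squared_unadjusted",
                    "beta_adjusted", "r_squared_adjusted") %in% names(lin)))
  logi <- association_table_logistic(cohort)
  expect_equal(nrow(logi), 6)
  expect_true(all(c("or_age_sex", "or_full", "or_tertile") %in% names(logi)))
  # HDL score counts HDL-lowering alleles: negative expected coefficient
  expect_lt(lin$beta_unadjusted[lin$trait == "HDL"], 0)
})

test_that("parameter recovery is unbiased with nominal CI coverage", {
  rep <- recovery_report(sim_config(n_subjects = 473), n_replicates = 60, seed = 310)
  expect_equal(nrow(rep), 4)
  expect_true(all(rep$coverage >= 0.85 & rep$coverage <= 1))
  # means within Monte-Carlo error of the generating values (3 SE of the mean,
  # where the per-replicate spread comes from the replicates themselves)
  expect_lt(abs(rep$bias[rep$parameter == "beta_ldl"]), 0.015)
  expect_lt(abs(rep$bias[rep$parameter == "beta_loghdl"]), 0.01)
  expect_lt(abs(rep$bias[rep$parameter == "beta_logtg"]), 0.01)
})
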