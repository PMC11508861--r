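#' Per-variant call rate
#'
#' Fraction of subjects with a non-missing genotype call.
#'
#' @param geno Genotype tibble (see [read_genotypes()]).
#' @param rsids Variants to report; defaults to every dosage column.
#' @return A tibble with `rsid` and `call_rate` (in `[0, 1]`).
#' @export
call_rate <- function(geno, rsids = NULL) {
  all_rs <- setdiff(names(geno), "subject_id")
  if (is.null(rsids)) rsids <- all_rs
  unknown <- setdiff(rsids, all_rs)
  if (length(unknown) > 0) {
    abort(paste0("unknown rsid(s): ", paste(unknown, collapse = ", ")))
  }
  tibble(
    rsid = rsids,
    call_rate = vapply(rsids, function(rs) mean(!is.na(geno[[rs]])), numeric(1),
                       USE.NAMES = FALSE)
  )
}

#' Risk-allele frequency
#'
#' Counts risk alleles over `2 x` the non-missing subjects; missing calls
#' are excluded from both numerator and denominator. By default the QC
#' report computes frequencies on the CAD-free subset, mirroring how
#' population frequencies are usually tabulated in case-control samples.
#'
#' @param geno Genotype tibble of risk-allele dosages.
#' @param rsids Variants to report; defaults to all dosage columns.
#' @param subset Optional logical vector (length `nrow(geno)`) selecting
#'   the subjects to use.
#' @return A tibble with `rsid`, `raf` and `n_used` (non-missing subjects).
#' @export
risk_allele_frequency <- function(geno, rsids = NULL, subset = NULL) {
  all_rs <- setdiff(names(geno), "subject_id")
  if (is.null(rsids)) rsids <- all_rs
  unknown <- setdiff(rsids, all_rs)
  if (length(unknown) > 0) {
    abort(paste0("unknown rsid(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(subset)) subset <- rep(TRUE, nrow(geno))
  rows <- purrr::map(rsids, function(rs) {
    d <- geno[[rs]][subset %in% TRUE]
    d <- d[!is.na(d)]
    if (length(d) == 0) {
      abort(paste0("no non-missing genotypes for ", rs, " in the requested subset"))
    }
    tibble(rsid = rs, raf = sum(d) / (2 * length(d)), n_used = length(d))
  })
  bind_rows(rows)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of Hardy-Weinberg proportions from genotype
#' counts. Conditional on the sample size and the allele count, the
#' heterozygote count has the exact distribution
#' \deqn{P(h) = \frac{n!\,2^h}{n_{AA}!\,h!\,n_{aa}!}\;
#'   \frac{n_A!\,n_a!}{(2n)!}}
#' and the two-sided p-value sums the probabilities of all heterozygote
#' counts no more probable than the observed one (probability-ordering
#' rule). The exact test is preferred over the chi-square approximation
#' because several panel variants have allele frequencies near 0 or 1
#' (e.g. risk-allele frequency 0.94), where expected cell counts are
#' small; the chi-square version is available via `method = "chisq"`.
#'
#' @param n_hom_risk,n_het,n_hom_other Genotype counts (vectors are
#'   recycled to a common length).
#' @param method `"exact"` (default) or `"chisq"` (1 df, no continuity
#'   correction).
#' @return Numeric vector of p-values in `(0, 1]`; monomorphic variants
#'   give 1.
#' @examples
#' hwe_exact_test(1, 0, 1)  # only the observed and h = 2 are possible
#' @export
hwe_exact_test <- function(n_hom_risk, n_het, n_hom_other, method = c("exact", "chisq")) {
  method <- match.arg(method)
  triples <- cbind(n_hom_risk, n_het, n_hom_other)
  if (any(triples < 0, na.rm = TRUE)) abort("genotype counts must be non-negative")
  if (any(rowSums(triples) < 1, na.rm = TRUE)) abort("at least one genotype is required")
  apply(triples, 1, function(tr) {
    if (anyNA(tr)) return(NA_real_)
    if (method == "chisq") hwe_chisq_one(tr[1], tr[2], tr[3]) else hwe_exact_one(tr[1], tr[2], tr[3])
  })
}

# Exact conditional p for one (hom_risk, het, hom_other) triple.
# Works in log space; robust for n in the thousands.
hwe_exact_one <- function(n_rr, n_het, n_oo) {
  n <- n_rr + n_het + n_oo
  n_a <- 2 * n_rr + n_het              # risk-allele count
  n_minor <- min(n_a, 2 * n - n_a)
  h <- hwe_support(n, n_minor)
  if (length(h) == 1) return(1)
  logp <- hwe_log_prob(n, n_minor, h)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_het, h)]
  # tolerance guards ties against floating-point noise
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

# Valid heterozygote counts given n subjects and n_minor minor alleles.
hwe_support <- function(n, n_minor) {
  h <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  h
}

# Log conditional probability of each heterozygote count.
hwe_log_prob <- function(n, n_minor, h) {
  n_major <- 2 * n - n_minor
  lfactorial(n) - lfactorial((n_minor - h) / 2) - lfactorial(h) -
    lfactorial((n_major - h) / 2) + h * log(2) +
    lfactorial(n_minor) + lfactorial(n_major) - lfactorial(2 * n)
}

hwe_chisq_one <- function(n_rr, n_het, n_oo) {
  n <- n_rr + n_het + n_oo
  p <- (2 * n_rr + n_het) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  stat <- sum((c(n_rr, n_het, n_oo) - expected)^2 / expected)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Panel-wide genotype quality control
#'
#' Computes, for every panel variant, the call rate, genotype counts,
#' risk-allele frequency and exact Hardy-Weinberg p-value, and flags
#' whether the variant passes QC: call rate at or above `min_call_rate`
#' and HWE p-value above the Bonferroni-style family threshold
#' `hwe_alpha / n_tests` (0.05/13 = 3.85e-3 with the defaults). RAF and
#' the HWE test use the CAD-free subjects when a `cad` column is supplied
#' via `cohort` (configurable with `hwe_subset`).
#'
#' @param geno Genotype tibble.
#' @param panel Variant panel; rows restricted to columns present in `geno`.
#' @param cohort Optional cohort tibble with `subject_id` and `cad`, used
#'   to restrict RAF/HWE to CAD-free subjects.
#' @param min_call_rate Minimum acceptable call rate (default 0.95).
#' @param hwe_alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of tests in the family (default: panel size).
#' @param hwe_subset `"controls"` (default; CAD-free subjects when
#'   available) or `"all"`.
#' @return A tibble with one row per variant: `rsid`, `gene`,
#'   `risk_allele`, `other_allele`, `call_rate`, `n_hom_risk`, `n_het`,
#'   `n_hom_other`, `raf`, `hwe_p`, `pass`.
#' @export
qc_panel <- function(geno, panel = ac_panel(), cohort = NULL,
                     min_call_rate = 0.95, hwe_alpha = 0.05,
                     n_tests = NULL, hwe_subset = c("controls", "all")) {
  hwe_subset <- match.arg(hwe_subset)
  validate_panel(panel)
  stopifnot(min_call_rate > 0, min_call_rate <= 1)
  rsids <- intersect(panel$rsid, names(geno))
  if (length(rsids) == 0) abort("no panel variants present in the genotype table")
  if (is.null(n_tests)) n_tests <- length(rsids)
  threshold <- hwe_alpha / n_tests
  subset <- rep(TRUE, nrow(geno))
  if (hwe_subset == "controls" && !is.null(cohort) && "cad" %in% names(cohort)) {
    cad <- cohort$cad[match(geno$subject_id, cohort$subject_id)]
    subset <- !(cad %in% TRUE)
  }
  rows <- purrr::map(rsids, function(rs) {
    d_all <- geno[[rs]]
    d <- d_all[subset]
    d <- d[!is.na(d)]
    counts <- c(sum(d == 2), sum(d == 1), sum(d == 0))
    tibble(
      rsid = rs,
      call_rate = mean(!is.na(d_all)),
      n_hom_risk = counts[1], n_het = counts[2], n_hom_other = counts[3],
      raf = if (sum(counts) > 0) (2 * counts[1] + counts[2]) / (2 * sum(counts)) else NA_real_,
      hwe_p = if (sum(counts) > 0) hwe_exact_test(counts[1], counts[2], counts[3]) else NA_real_
    )
  })
  report <- bind_rows(rows) %>%
    left_join(panel %>% select("rsid", "gene", "risk_allele", "other_allele"),
              by = "rsid") %>%
    mutate(pass = .data$call_rate >= min_call_rate & .data$hwe_p > threshold) %>%
    select("rsid", "gene", "risk_allele", "other_allele", "call_rate",
           "n_hom_risk", "n_het", "n_hom_other", "raf", "hwe_p", "pass")
  attr(report, "hwe_threshold") <- threshold
  report
}
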