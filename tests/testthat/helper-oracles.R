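# Independent oracles used to cross-check the package's statistics.

# Exact conditional HWE p-value by direct enumeration of genotype-count
# triples. Weights count ordered assignments of genotypes to n subjects
# (choose-based), normalised numerically -- a different route from the
# package's log-factorial allele-count formula.
hwe_oracle <- function(n_rr, n_het, n_oo) {
  n <- n_rr + n_het + n_oo
  n_a <- 2 * n_rr + n_het
  support <- list()
  for (h in 0:n) {
    a2 <- (n_a - h) / 2
    c2 <- n - h - a2
    if (a2 >= 0 && c2 >= 0 && a2 == round(a2)) {
      w <- choose(n, a2) * choose(n - a2, h) * 2^h
      support[[length(support) + 1]] <- c(h = h, w = w)
    }
  }
  m <- do.call(rbind, support)
  probs <- m[, "w"] / sum(m[, "w"])
  obs <- probs[m[, "h"] == n_het]
  sum(probs[probs <= obs * (1 + 1e-9)])
}

# AUC by exhaustive case-control pair counting, ties scored one half.
auc_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (x in cases) {
    for (y in controls) {
      total <- total + (x > y) + 0.5 * (x == y)
    }
  }
  total / (length(cases) * length(controls))
}

# Per-subject brute-force allele-count score, independent of compute_prs.
brute_force_score <- function(geno, members, e2 = NULL) {
  vapply(seq_len(nrow(geno)), function(i) {
    s <- 0
    for (rs in members) s <- s + geno[[rs]][i]
    if (!is.null(e2)) s <- s + e2[i]
    s
  }, numeric(1))
}

# Small deterministic genotype fixture on the real panel.
make_geno <- function(dosages) {
  stopifnot(is.list(dosages))
  n <- length(dosages[[1]])
  out <- tibble::tibble(subject_id = sprintf("S%02d", seq_len(n)))
  for (rs in names(dosages)) out[[rs]] <- as.integer(dosages[[rs]])
  out
}

# Complete-genotype cohort fixture shared across model tests.
small_cohort <- function(n = 400, seed = 101, ...) {
  sim <- simulate_cohort(sim_config(n_subjects = n, ...), seed = seed)
  cohort_table(sim)
}
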