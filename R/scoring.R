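#' Compute unweighted polygenic risk scores
#'
#' For each score definition, sums risk-allele dosages over the member
#' SNPs (0/1/2 per locus); the TG score additionally adds the APOE
#' epsilon2 haplotype dosage as an ordinary 0/1/2 component. With
#' `missing_policy = "mean_impute"` (the default) a missing dosage is
#' replaced by twice the cohort risk-allele frequency at that variant, so
#' every subject receives a (possibly fractional) score and model sample
#' sizes match the full cohort; `"complete_case"` leaves the score
#' missing for any subject with a missing member genotype.
#'
#' Note the HDL score counts HDL-*lowering* alleles: a higher HDL-PRS
#' predicts a lower HDL level, so its expected regression coefficient
#' against (log) HDL is negative.
#'
#' @param geno Genotype tibble of risk-allele dosages.
#' @param defs Score definitions (see [default_score_definitions()]).
#' @param apoe_calls Optional tibble from [apoe_from_genotypes()]; derived
#'   from `geno` when absent and a definition needs the epsilon2 dosage.
#' @param missing_policy `"mean_impute"` (default) or `"complete_case"`.
#' @return A tibble with one row per subject and trait: `subject_id`,
#'   `trait`, `score`, `n_markers` (components used), `complete`
#'   (`FALSE` when any component was imputed or missing).
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 50), seed = 1)
#' compute_prs(cohort$genotypes)
#' @export
compute_prs <- function(geno, defs = default_score_definitions(),
                        apoe_calls = NULL,
                        missing_policy = c("mean_impute", "complete_case")) {
  missing_policy <- match.arg(missing_policy)
  needs_apoe <- any(defs$include_apoe_e2)
  if (needs_apoe && is.null(apoe_calls)) apoe_calls <- apoe_from_genotypes(geno)
  purrr::pmap(defs, function(trait, members, include_apoe_e2) {
    absent <- setdiff(members, names(geno))
    if (length(absent) > 0) {
      abort(paste0(trait, " score references rsids absent from the genotype table: ",
                   paste(absent, collapse = ", ")))
    }
    dosage <- as.matrix(geno[, members, drop = FALSE])
    if (include_apoe_e2) {
      e2 <- epsilon2_dosage(apoe_calls)[match(geno$subject_id, apoe_calls$subject_id)]
      dosage <- cbind(dosage, apoe_e2 = e2)
    }
    any_missing <- apply(dosage, 1, anyNA)
    if (missing_policy == "mean_impute") {
      for (j in seq_len(ncol(dosage))) {
        col <- dosage[, j]
        if (anyNA(col)) {
          if (all(is.na(col))) {
            abort(paste0("cannot impute ", colnames(dosage)[j],
                         ": all genotypes missing"))
          }
          dosage[is.na(col), j] <- 2 * sum(col, na.rm = TRUE) / (2 * sum(!is.na(col)))
        }
      }
      score <- rowSums(dosage)
    } else {
      score <- rowSums(dosage)  # stays NA where any component is missing
    }
    tibble(
      subject_id = geno$subject_id,
      trait = trait,
      score = score,
      n_markers = ncol(dosage),
      complete = !any_missing
    )
  }) %>% bind_rows()
}

#' Attach PRS columns to a cohort table
#'
#' Computes the three scores with [compute_prs()] and joins them to the
#' cohort as wide columns `ldl_prs`, `hdl_prs`, `tg_prs` (plus
#' `ldl_prs_complete` etc.).
#'
#' @inheritParams compute_prs
#' @param cohort Cohort tibble with `subject_id`.
#' @return `cohort` with score columns added.
#' @export
add_prs <- function(cohort, geno, defs = default_score_definitions(),
                    missing_policy = c("mean_impute", "complete_case")) {
  scores <- compute_prs(geno, defs, missing_policy = match.arg(missing_policy))
  wide <- scores %>%
    mutate(trait = paste0(tolower(.data$trait), "_prs")) %>%
    tidyr::pivot_wider(id_cols = "subject_id", names_from = "trait",
                       values_from = c("score", "complete"),
                       names_glue = "{trait}{ifelse(.value == 'score', '', '_complete')}")
  left_join(cohort, wide, by = "subject_id")
}

#' Bin scores into tertiles or quartiles
#'
#' Assigns each scored subject to one of `k` bins at the empirical
#' quantiles of the (discrete) score distribution. A tied score value is
#' assigned wholly to the lower bin: subjects fall in bin `b` when their
#' score is above cutpoint `b - 1` and at or below cutpoint `b`. On
#' heavily tied integer scores the bin shares are therefore unequal
#' (e.g. a "top quartile" holding far less than 25% of subjects), which
#' is the behaviour expected of allele-count scores.
#'
#' @param scores A tibble with `subject_id` and `score` (one trait), or
#'   the long output of [compute_prs()] filtered to one trait.
#' @param k Number of bins: 3 (tertiles) or 4 (quartiles).
#' @return A tibble `subject_id`, `score`, `bin` (integer `1..k`), with
#'   the cutpoints in attribute `"cutpoints"`. Subjects with missing
#'   scores get `NA` bins.
#' @export
bin_score <- function(scores, k = 3) {
  stopifnot(k %in% c(3, 4))
  if (!all(c("subject_id", "score") %in% names(scores))) {
    abort("scores must have subject_id and score columns")
  }
  if ("trait" %in% names(scores) && length(unique(scores$trait)) > 1) {
    abort("bin_score expects scores for a single trait; filter first")
  }
  s <- scores$score
  obs <- s[!is.na(s)]
  if (length(unique(obs)) < k) {
    abort(paste0("need at least ", k, " distinct score values to form ", k, " bins"))
  }
  cuts <- quantile(obs, probs = seq_len(k - 1) / k, type = 1, names = FALSE)
  bin <- 1L + vapply(s, function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(x > cuts)
  }, integer(1))
  out <- tibble(subject_id = scores$subject_id, score = s, bin = bin)
  attr(out, "cutpoints") <- cuts
  attr(out, "k") <- k
  out
}
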