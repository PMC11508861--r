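#' Derive clinical risk-factor flags from the phenotype record
#'
#' Adds guideline-style clinical flags to the cohort table:
#'
#' * `obesity`: BMI >= 30 kg/m2;
#' * `hypertension`: SBP >= 140 mmHg, or DBP >= 90 mmHg, or current
#'   antihypertensive medication. With no blood-pressure reading and no
#'   (positive) medication flag the status is undeterminable and left
#'   missing; subjects with missing hypertension are dropped (with a
#'   message) from models that adjust for it;
#' * `diabetes`: history of diabetes or prescribed hypoglycaemic agents
#'   (the `diabetes_history` input flag covers both);
#' * `smoking`: current regular smoker;
#' * `alcohol`: regular consumption (more than three days per week);
#' * `hypercholesterolemia`: history of hypercholesterolemia or current
#'   lipid-lowering therapy.
#'
#' The derivation is deterministic and idempotent; missing inputs
#' propagate to missing flags.
#'
#' @param cohort Phenotype tibble (see [read_phenotypes()]).
#' @return `cohort` with logical columns `obesity`, `hypertension`,
#'   `diabetes`, `smoking`, `alcohol`, `hypercholesterolemia` added
#'   (replaced if already present).
#' @examples
#' tibble::tibble(
#'   subject_id = "S1", bmi = 31, sbp = 138, dbp = 85,
#'   on_antihypertensive = FALSE, on_lipid_lowering = FALSE,
#'   diabetes_history = FALSE, smoker_current = FALSE,
#'   alcohol_regular = FALSE
#' ) |> derive_clinical_flags()
#' @export
derive_clinical_flags <- function(cohort) {
  need <- c("bmi", "sbp", "dbp", "on_antihypertensive", "on_lipid_lowering",
            "diabetes_history", "smoker_current", "alcohol_regular")
  for (col in setdiff(need, names(cohort))) cohort[[col]] <- NA
  # a history column is optional; when it was never collected, the flag is
  # driven by lipid-lowering therapy alone
  hchol_hist <- if ("hypercholesterolemia_history" %in% names(cohort)) {
    cohort$hypercholesterolemia_history
  } else {
    rep(FALSE, nrow(cohort))
  }
  cohort %>%
    mutate(
      obesity = .data$bmi >= 30,
      hypertension = flag_hypertension(.data$sbp, .data$dbp, .data$on_antihypertensive),
      diabetes = .data$diabetes_history,
      smoking = .data$smoker_current,
      alcohol = .data$alcohol_regular,
      hypercholesterolemia = or_na(hchol_hist, cohort$on_lipid_lowering)
    )
}

# SBP/DBP thresholds or medication. Base R's `|` is already three-valued
# (TRUE | NA is TRUE, FALSE | NA is NA), which is exactly the rule: any
# definite TRUE wins, a definite FALSE needs all components determinable.
flag_hypertension <- function(sbp, dbp, meds) {
  (sbp >= 140) | (dbp >= 90) | meds
}

or_na <- function(a, b) a | b
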