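#' Friedewald LDL estimate (mmol/L)
#'
#' `ldl = tc - hdl - tg / 2.2`, the mmol/L form of the Friedewald
#' equation (TG/5 in mg/dL). Valid only below a triglyceride level of
#' 3.9 mmol/L (340 mg/dL); at or above that the function refuses and the
#' apolipoprotein-B-based estimate ([planella_ldl()]) must be used
#' instead.
#'
#' @param tc,hdl,tg Total cholesterol, HDL and triglycerides in mmol/L.
#' @return LDL cholesterol in mmol/L.
#' @examples
#' friedewald_ldl(4.92, 1.36, 1.11)
#' @export
friedewald_ldl <- function(tc, hdl, tg) {
  if (any(c(tc, hdl, tg) < 0, na.rm = TRUE)) abort("lipid inputs must be non-negative")
  if (any(tg >= 3.9, na.rm = TRUE)) {
    abort("Friedewald formula is invalid at TG >= 3.9 mmol/L; use planella_ldl()")
  }
  tc - hdl - tg / 2.2
}

#' apoB-based LDL estimate for high-triglyceride subjects
#'
#' Linear estimate of LDL cholesterol from apolipoprotein B, used where
#' the Friedewald equation breaks down (TG >= 3.9 mmol/L). The
#' coefficients of the original published calibration are not bundled;
#' the default constants (`slope = 2.7` mmol/L per g/L apoB,
#' `intercept = 0`) are an approximate physiologic calibration chosen by
#' this package (apoB 1.0 g/L maps to LDL 2.7 mmol/L) and are fully
#' pluggable -- supply the published coefficients via `constants` for any
#' substantive use.
#'
#' @param apob Apolipoprotein B in g/L.
#' @param constants List with elements `slope` and `intercept`, e.g. from
#'   [planella_constants()].
#' @return LDL cholesterol in mmol/L (`NA` where `apob` is missing).
#' @export
planella_ldl <- function(apob, constants = planella_constants()) {
  if (any(apob <= 0, na.rm = TRUE)) abort("apob must be positive")
  constants$intercept + constants$slope * apob
}

#' @rdname planella_ldl
#' @param slope,intercept Linear coefficients (mmol/L per g/L; mmol/L).
#' @export
planella_constants <- function(slope = 2.7, intercept = 0) {
  stopifnot(is.numeric(slope), is.numeric(intercept), slope > 0)
  list(slope = slope, intercept = intercept)
}

#' Derive LDL for a cohort with the Friedewald/apoB switch
#'
#' Fills the `ldl` column where missing: the Friedewald estimate when
#' TG < 3.9 mmol/L, the apoB-based estimate at TG >= 3.9 mmol/L, and
#' missing (with a message counting such subjects) when TG is high but
#' apoB is unavailable. A measured `ldl` value is kept untouched. The
#' provenance is recorded per subject in `ldl_method` (`"measured"`,
#' `"friedewald"`, `"planella"` or `NA`).
#'
#' @param cohort Cohort tibble with `tc`, `hdl`, `tg` and optionally
#'   `ldl`, `apob`.
#' @param constants apoB calibration, see [planella_constants()].
#' @return `cohort` with `ldl` and `ldl_method` columns.
#' @export
derive_ldl <- function(cohort, constants = planella_constants()) {
  if (!"ldl" %in% names(cohort)) cohort$ldl <- NA_real_
  if (!"apob" %in% names(cohort)) cohort$apob <- NA_real_
  measured <- !is.na(cohort$ldl)
  low_tg <- !is.na(cohort$tg) & cohort$tg < 3.9
  can_friedewald <- !measured & low_tg & !is.na(cohort$tc) & !is.na(cohort$hdl)
  can_planella <- !measured & !is.na(cohort$tg) & cohort$tg >= 3.9 & !is.na(cohort$apob)
  ldl <- cohort$ldl
  ldl[can_friedewald] <- friedewald_ldl(cohort$tc[can_friedewald],
                                        cohort$hdl[can_friedewald],
                                        cohort$tg[can_friedewald])
  ldl[can_planella] <- planella_ldl(cohort$apob[can_planella], constants)
  method <- rep(NA_character_, nrow(cohort))
  method[measured] <- "measured"
  method[can_friedewald] <- "friedewald"
  method[can_planella] <- "planella"
  unresolved <- sum(!measured & !can_friedewald & !can_planella &
                      !is.na(cohort$tg) & cohort$tg >= 3.9)
  if (unresolved > 0) {
    inform(paste0(unresolved, " subject(s) with TG >= 3.9 mmol/L lack apoB; LDL left missing"))
  }
  cohort$ldl <- ldl
  cohort$ldl_method <- method
  cohort
}

#' Convert lipid concentrations between mmol/L and mg/dL
#'
#' Cholesterol-class analytes (total, LDL and HDL cholesterol) convert at
#' 38.67 mg/dL per mmol/L and triglycerides at 88.57 mg/dL per mmol/L
#' (molar masses of cholesterol and average triglyceride); the constants
#' are fixed, not configurable.
#'
#' @param x Concentration(s).
#' @param analyte `"cholesterol"` or `"triglyceride"`.
#' @return The converted concentration(s).
#' @examples
#' mmol_to_mgdl(0.144, "cholesterol")  # per-allele LDL effect, 5.57 mg/dL
#' @export
mmol_to_mgdl <- function(x, analyte = c("cholesterol", "triglyceride")) {
  x * conversion_factor(match.arg(analyte))
}

#' @rdname mmol_to_mgdl
#' @export
mgdl_to_mmol <- function(x, analyte = c("cholesterol", "triglyceride")) {
  x / conversion_factor(match.arg(analyte))
}

conversion_factor <- function(analyte) {
  switch(analyte, cholesterol = 38.67, triglyceride = 88.57)
}

#' Interpret a log-scale regression coefficient per risk allele
#'
#' For outcomes modelled on the natural-log scale (HDL and TG), a
#' per-allele coefficient `b` means a multiplicative change `exp(b)` per
#' additional risk allele. `percent_change_per_allele()` returns
#' `100 * (exp(b) - 1)`; `absolute_change_at_mean()` returns the implied
#' absolute change `mean_level * (exp(b) - 1)` at a given mean level.
#'
#' @param beta_log Natural-log-scale coefficient.
#' @param mean_level Mean outcome level (mmol/L), positive.
#' @return Percent change, or absolute change in mmol/L.
#' @examples
#' percent_change_per_allele(-0.021)       # -2.1% HDL per allele
#' absolute_change_at_mean(0.018, 1.11)    # +0.02 mmol/L TG per allele
#' @export
percent_change_per_allele <- function(beta_log) {
  100 * (exp(beta_log) - 1)
}

#' @rdname percent_change_per_allele
#' @export
absolute_change_at_mean <- function(beta_log, mean_level) {
  if (any(mean_level <= 0, na.rm = TRUE)) abort("mean_level must be positive")
  mean_level * (exp(beta_log) - 1)
}

#' Guideline lipid threshold categories
#'
#' Flags each subject against the intervention thresholds used in the
#' analysis, with strict inequalities: LDL > 2.6 mmol/L (100 mg/dL),
#' LDL > 3.0 (116), HDL < 1.03 (40), HDL > 1.55 (60), TG > 1.69 (150)
#' and TG > 2.26 mmol/L (200 mg/dL). Missing lipids give missing flags.
#'
#' @param cohort Cohort tibble with `ldl`, `hdl`, `tg` columns (mmol/L).
#' @return `cohort` with logical columns `ldl_gt_2_6`, `ldl_gt_3_0`,
#'   `hdl_lt_1_03`, `hdl_gt_1_55`, `tg_gt_1_69`, `tg_gt_2_26`.
#' @export
categorize_lipids <- function(cohort) {
  cohort %>%
    mutate(
      ldl_gt_2_6 = .data$ldl > 2.6,
      ldl_gt_3_0 = .data$ldl > 3.0,
      hdl_lt_1_03 = .data$hdl < 1.03,
      hdl_gt_1_55 = .data$hdl > 1.55,
      tg_gt_1_69 = .data$tg > 1.69,
      tg_gt_2_26 = .data$tg > 2.26
    )
}

#' Lipid threshold table
#'
#' The six guideline thresholds with both unit systems, for reporting.
#'
#' @return A tibble with `flag`, `lipid`, `direction`, `mmol_l`, `mg_dl`.
#' @export
lipid_thresholds <- function() {
  tibble(
    flag = c("ldl_gt_2_6", "ldl_gt_3_0", "hdl_lt_1_03", "hdl_gt_1_55",
             "tg_gt_1_69", "tg_gt_2_26"),
    lipid = c("ldl", "ldl", "hdl", "hdl", "tg", "tg"),
    direction = c(">", ">", "<", ">", ">", ">"),
    mmol_l = c(2.6, 3.0, 1.03, 1.55, 1.69, 2.26),
    mg_dl = c(100, 116, 40, 60, 150, 200)
  )
}
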