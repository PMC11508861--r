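#' Default covariate sets for each model family
#'
#' The fully adjusted covariate sets: LDL models adjust for sex, age,
#' BMI, diabetes and smoking; HDL for sex, age, BMI, diabetes and
#' alcohol; TG for sex, age, BMI, diabetes, alcohol and hypertension;
#' CAD models for age, sex, hypertension, diabetes and smoking.
#'
#' @param model `"LDL"`, `"HDL"`, `"TG"` or `"CAD"`.
#' @return Character vector of cohort column names.
#' @export
default_covariates <- function(model = c("LDL", "HDL", "TG", "CAD")) {
  switch(match.arg(model),
    LDL = c("sex", "age", "bmi", "diabetes", "smoking"),
    HDL = c("sex", "age", "bmi", "diabetes", "alcohol"),
    TG  = c("sex", "age", "bmi", "diabetes", "alcohol", "hypertension"),
    CAD = c("age", "sex", "hypertension", "diabetes", "smoking")
  )
}

# Rows eligible for lipid-level / lipid-threshold models: subjects on
# lipid-lowering medication and/or with CAD are excluded.
lipid_model_filter <- function(cohort) {
  drop <- (cohort$cad %in% TRUE) | (cohort$on_lipid_lowering %in% TRUE)
  !drop
}

# Assemble a complete-case model frame; records filter/NA drop counts.
model_frame <- function(cohort, cols, filter = NULL) {
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  keep <- if (is.null(filter)) rep(TRUE, nrow(cohort)) else filter
  df <- cohort[keep, cols, drop = FALSE]
  cc <- stats::complete.cases(df)
  out <- df[cc, , drop = FALSE]
  attr(out, "n_excluded_filter") <- sum(!keep)
  attr(out, "n_dropped_na") <- sum(!cc)
  out
}

wald_ci <- function(fit, term, level = 0.95) {
  est <- coef(fit)[[term]]
  se <- sqrt(vcov(fit)[term, term])
  z <- qnorm(1 - (1 - level) / 2)
  c(estimate = est, conf.low = est - z * se, conf.high = est + z * se,
    std.error = se)
}

#' Linear association of a lipid level with its PRS
#'
#' Ordinary least squares of the lipid level on the allele-count PRS
#' (entered as a continuous variable), with HDL and TG log-transformed
#' (natural log) before fitting because of their skewed distributions.
#' Subjects on lipid-lowering medication and/or with CAD are excluded,
#' and the analysis is complete-case on the model columns. Two models
#' are fitted: PRS only (its r-squared is the "unadjusted explained
#' variability") and PRS plus covariates (the adjusted model).
#'
#' @param cohort Cohort tibble with the PRS column (see [add_prs()]),
#'   lipid levels, covariates and `cad`/`on_lipid_lowering` flags.
#' @param trait `"LDL"`, `"HDL"` or `"TG"`.
#' @param covariates Adjustment set; defaults to
#'   `default_covariates(trait)`. Use `character(0)` for no adjustment.
#' @param prs_col PRS column name; default `"<trait>_prs"`.
#' @param exclude Logical: apply the CAD / lipid-medication exclusion
#'   (default `TRUE`).
#' @return A `prs_linear` object; see [tidy.prs_linear()] and
#'   [glance.prs_linear()].
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 400), seed = 7)
#' fit <- fit_prs_linear(cohort_table(sim), "LDL")
#' glance(fit)
#' @export
fit_prs_linear <- function(cohort, trait = c("LDL", "HDL", "TG"),
                           covariates = NULL, prs_col = NULL, exclude = TRUE) {
  trait <- match.arg(trait)
  if (is.null(covariates)) covariates <- default_covariates(trait)
  if (is.null(prs_col)) prs_col <- paste0(tolower(trait), "_prs")
  outcome_col <- tolower(trait)
  log_outcome <- trait %in% c("HDL", "TG")
  cols <- c(outcome_col, prs_col, covariates)
  df <- model_frame(cohort, cols,
                    filter = if (exclude) lipid_model_filter(cohort) else NULL)
  if (log_outcome) {
    if (any(df[[outcome_col]] <= 0)) abort("cannot log-transform non-positive lipid values")
    df$.y <- log(df[[outcome_col]])
  } else {
    df$.y <- df[[outcome_col]]
  }
  if (nrow(df) < length(covariates) + 3) abort("too few complete cases to fit the model")
  f_prs <- as.formula(paste(".y ~", backtick(prs_col)))
  f_full <- as.formula(paste(".y ~", paste(backtick(c(prs_col, covariates)), collapse = " + ")))
  fit_prs_only <- lm(f_prs, data = df)
  fit_full <- lm(f_full, data = df)
  if (any(is.na(coef(fit_full)))) abort("rank-deficient design in the adjusted model")
  structure(
    list(
      trait = trait, outcome = if (log_outcome) paste0("log_", outcome_col) else outcome_col,
      prs_col = prs_col, covariates = covariates,
      fit_prs_only = fit_prs_only, fit_full = fit_full,
      n_used = nrow(df),
      n_excluded_filter = attr(df, "n_excluded_filter"),
      n_dropped_na = attr(df, "n_dropped_na")
    ),
    class = "prs_linear"
  )
}

backtick <- function(x) {
  if (length(x) == 0) return(character(0))
  paste0("`", x, "`")
}

#' @describeIn fit_prs_linear Per-term coefficients of the adjusted model
#'   (Wald 95% CIs).
#' @param x,model A `prs_linear` object.
#' @param adjusted Tidy the adjusted (default) or PRS-only model.
#' @param ... Unused.
#' @export
tidy.prs_linear <- function(x, adjusted = TRUE, ...) {
  fit <- if (adjusted) x$fit_full else x$fit_prs_only
  s <- summary(fit)$coefficients
  z <- qnorm(0.975)
  tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2], statistic = s[, 3], p.value = s[, 4],
    conf.low = s[, 1] - z * s[, 2], conf.high = s[, 1] + z * s[, 2]
  )
}

#' @describeIn fit_prs_linear One-row summary: per-allele effect with
#'   95% CI and p (adjusted model), and explained variability of both
#'   the PRS-only and the adjusted model.
#' @export
glance.prs_linear <- function(x, ...) {
  term <- backtick_match(x$fit_full, x$prs_col)
  ci_adj <- wald_ci(x$fit_full, term)
  p_adj <- summary(x$fit_full)$coefficients[term, 4]
  term0 <- backtick_match(x$fit_prs_only, x$prs_col)
  ci_un <- wald_ci(x$fit_prs_only, term0)
  p_un <- summary(x$fit_prs_only)$coefficients[term0, 4]
  tibble(
    trait = x$trait, outcome = x$outcome,
    beta_unadjusted = ci_un[["estimate"]],
    conf.low_unadjusted = ci_un[["conf.low"]],
    conf.high_unadjusted = ci_un[["conf.high"]],
    p_unadjusted = p_un,
    r_squared_unadjusted = r_squared0(x$fit_prs_only),
    beta_adjusted = ci_adj[["estimate"]],
    conf.low_adjusted = ci_adj[["conf.low"]],
    conf.high_adjusted = ci_adj[["conf.high"]],
    p_adjusted = p_adj,
    r_squared_adjusted = r_squared0(x$fit_full),
    n_used = x$n_used
  )
}

# r-squared with the zero-variance outcome convention: no variance, nothing
# explained. (summary.lm returns garbage when both MSS and RSS vanish.)
r_squared0 <- function(fit) {
  y <- stats::model.response(stats::model.frame(fit))
  tss <- sum((y - mean(y))^2)
  if (tss < 1e-12) return(0)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (is.nan(r2)) 0 else r2
}

# lm/glm coefficient names carry the backticks only when needed.
backtick_match <- function(fit, col) {
  cand <- c(col, backtick(col))
  hit <- cand[cand %in% names(coef(fit))]
  if (length(hit) == 0) abort(paste0("term ", col, " not found in fit"))
  hit[1]
}

#' @export
print.prs_linear <- function(x, ...) {
  cat("<prs_linear> ", x$trait, "-PRS on ", x$outcome, "\n", sep = "")
  g <- glance(x)
  cat(sprintf("  unadjusted beta %.4f (%.4f, %.4f), p = %.3g, r2 = %.3f\n",
              g$beta_unadjusted, g$conf.low_unadjusted, g$conf.high_unadjusted,
              g$p_unadjusted, g$r_squared_unadjusted))
  cat(sprintf("  adjusted   beta %.4f (%.4f, %.4f), p = %.3g, r2 = %.3f\n",
              g$beta_adjusted, g$conf.low_adjusted, g$conf.high_adjusted,
              g$p_adjusted, g$r_squared_adjusted))
  cat("  n =", x$n_used, "\n")
  invisible(x)
}

#' Logistic association of a binary outcome with a PRS
#'
#' Maximum-likelihood logistic regression of a binary outcome (a lipid
#' threshold flag or CAD) on the continuous allele-count PRS, with the
#' per-allele odds ratio `exp(coefficient)` and a Wald 95% CI. Lipid
#' threshold outcomes apply the CAD / lipid-medication exclusion;
#' CAD models use the whole cohort.
#'
#' @param cohort Cohort tibble.
#' @param outcome Binary outcome column, e.g. `"ldl_gt_3_0"` or `"cad"`.
#' @param prs_col PRS column name.
#' @param covariates Adjustment set (character vector, possibly empty).
#' @param exclude Apply the lipid-model exclusion; default `TRUE` except
#'   when `outcome == "cad"`.
#' @return A `prs_logistic` object; `tidy()` gives per-term ORs,
#'   `glance()` the per-allele OR row. Complete separation is flagged
#'   (`separation = TRUE`) and estimates are reported as `NA`.
#' @export
fit_prs_logistic <- function(cohort, outcome, prs_col,
                             covariates = character(0),
                             exclude = !identical(outcome, "cad")) {
  cols <- c(outcome, prs_col, covariates)
  df <- model_frame(cohort, cols,
                    filter = if (exclude) lipid_model_filter(cohort) else NULL)
  y <- df[[outcome]]
  if (length(unique(y)) < 2) abort(paste0("outcome ", outcome, " has a single class"))
  f <- as.formula(paste(backtick(outcome), "~",
                        paste(backtick(c(prs_col, covariates)), collapse = " + ")))
  fitted <- glm_flag_separation(f, df)
  fit <- fitted$fit
  separation <- fitted$separation
  structure(
    list(outcome = outcome, prs_col = prs_col, covariates = covariates,
         fit = fit, separation = separation, n_used = nrow(df),
         n_excluded_filter = attr(df, "n_excluded_filter"),
         n_dropped_na = attr(df, "n_dropped_na")),
    class = "prs_logistic"
  )
}

# Logistic fit that flags (quasi-)separation / non-convergence instead of
# emitting glm.fit warnings.
glm_flag_separation <- function(f, df) {
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = df, family = binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("did not converge", msg)) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!fit$converged) separation <- TRUE
  list(fit = fit, separation = separation)
}

#' @describeIn fit_prs_logistic Per-term odds ratios with Wald 95% CIs.
#' @param x A `prs_logistic` object.
#' @param ... Unused.
#' @export
tidy.prs_logistic <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  z <- qnorm(0.975)
  out <- tibble(
    term = rownames(s),
    estimate = s[, 1], std.error = s[, 2], statistic = s[, 3], p.value = s[, 4],
    or = exp(s[, 1]),
    or.conf.low = exp(s[, 1] - z * s[, 2]),
    or.conf.high = exp(s[, 1] + z * s[, 2])
  )
  if (x$separation) {
    out <- out %>% mutate(across(c("estimate", "std.error", "statistic",
                                   "p.value", "or", "or.conf.low", "or.conf.high"),
                                 ~ NA_real_))
  }
  out
}

#' @describeIn fit_prs_logistic One-row per-allele OR summary.
#' @export
glance.prs_logistic <- function(x, ...) {
  if (x$separation) {
    return(tibble(outcome = x$outcome, or_per_allele = NA_real_,
                  conf.low = NA_real_, conf.high = NA_real_, p = NA_real_,
                  n_used = x$n_used, separation = TRUE))
  }
  term <- backtick_match(x$fit, x$prs_col)
  ci <- wald_ci(x$fit, term)
  p <- summary(x$fit)$coefficients[term, 4]
  tibble(outcome = x$outcome, or_per_allele = exp(ci[["estimate"]]),
         conf.low = exp(ci[["conf.low"]]), conf.high = exp(ci[["conf.high"]]),
         p = p, n_used = x$n_used, separation = FALSE)
}

#' @export
print.prs_logistic <- function(x, ...) {
  g <- glance(x)
  cat("<prs_logistic> ", x$prs_col, " -> ", x$outcome, "\n", sep = "")
  if (isTRUE(g$separation)) {
    cat("  complete separation: no estimate\n")
  } else {
    cat(sprintf("  OR per allele %.3f (%.3f, %.3f), p = %.3g, n = %d\n",
                g$or_per_allele, g$conf.low, g$conf.high, g$p, g$n_used))
  }
  invisible(x)
}

#' Tertile / quartile contrasts of a PRS against a binary outcome
#'
#' Logistic regression of a binary outcome on score-bin membership with
#' the lowest bin as reference. For tertiles (`k = 3`) the middle bin is
#' dropped and a single upper-vs-lower OR is returned; for quartiles
#' (`k = 4`) indicator terms give one OR per upper quartile (Q2, Q3, Q4
#' vs Q1).
#'
#' @param cohort Cohort tibble.
#' @param bins Bin assignment from [bin_score()] (same subjects).
#' @param outcome Binary outcome column.
#' @param covariates Adjustment set.
#' @param exclude Apply the lipid-model exclusion; default `TRUE` except
#'   for `"cad"`.
#' @return A `prs_bin_contrast` object; `tidy()` returns one row per
#'   contrast with OR, 95% CI and p.
#' @export
fit_bin_contrast <- function(cohort, bins, outcome,
                             covariates = character(0),
                             exclude = !identical(outcome, "cad")) {
  k <- attr(bins, "k")
  if (is.null(k)) k <- max(bins$bin, na.rm = TRUE)
  joined <- cohort %>%
    left_join(bins %>% select("subject_id", "bin"), by = "subject_id")
  if (k == 3) joined <- joined %>% filter(is.na(.data$bin) | .data$bin != 2L)
  joined$bin_f <- factor(joined$bin, levels = sort(unique(bins$bin)))
  cols <- c(outcome, "bin_f", covariates)
  df <- model_frame(joined, cols,
                    filter = if (exclude) lipid_model_filter(joined) else NULL)
  df$bin_f <- droplevels(df$bin_f)
  if (nlevels(df$bin_f) < 2) abort("empty bin after filtering")
  f <- as.formula(paste(backtick(outcome), "~",
                        paste(c("bin_f", backtick(covariates)), collapse = " + ")))
  fitted <- glm_flag_separation(f, df)
  structure(
    list(outcome = outcome, k = k, covariates = covariates, fit = fitted$fit,
         separation = fitted$separation, n_used = nrow(df)),
    class = "prs_bin_contrast"
  )
}

#' @describeIn fit_bin_contrast One row per bin contrast (vs the lowest
#'   bin): OR, Wald 95% CI, p.
#' @param x A `prs_bin_contrast` object.
#' @param ... Unused.
#' @export
tidy.prs_bin_contrast <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  terms <- grep("^bin_f", rownames(s), value = TRUE)
  z <- qnorm(0.975)
  out <- tibble(
    contrast = paste0("bin", sub("^bin_f", "", terms), "_vs_bin1"),
    or = exp(s[terms, 1]),
    or.conf.low = exp(s[terms, 1] - z * s[terms, 2]),
    or.conf.high = exp(s[terms, 1] + z * s[terms, 2]),
    p.value = s[terms, 4],
    n_used = x$n_used
  )
  if (isTRUE(x$separation)) {
    out <- out %>% mutate(across(c("or", "or.conf.low", "or.conf.high",
                                   "p.value"), ~ NA_real_))
  }
  out
}

#' Linear association table for the three lipid scores
#'
#' Fits the unadjusted and fully adjusted linear models for each trait
#' and assembles one row per score with per-allele effects, 95% CIs,
#' p-values and explained variability -- the layout of a standard
#' "PRS vs lipid level" results table.
#'
#' @param cohort Cohort tibble with `ldl_prs`/`hdl_prs`/`tg_prs`.
#' @param traits Traits to include.
#' @return A tibble with one row per trait (see [glance.prs_linear()]).
#' @export
association_table_linear <- function(cohort, traits = c("LDL", "HDL", "TG")) {
  purrr::map(traits, function(tr) glance(fit_prs_linear(cohort, tr))) %>%
    bind_rows()
}

#' Logistic association table for the six lipid thresholds
#'
#' For each guideline threshold, fits the age- and sex-adjusted and the
#' fully adjusted per-allele logistic models of the corresponding PRS,
#' plus the upper-vs-lower tertile contrast (age- and sex-adjusted).
#'
#' @param cohort Cohort tibble with PRS columns and threshold flags (see
#'   [categorize_lipids()]).
#' @return A tibble with six rows (one per threshold).
#' @export
association_table_logistic <- function(cohort) {
  thr <- lipid_thresholds()
  trait_of <- c(ldl = "LDL", hdl = "HDL", tg = "TG")
  rows <- purrr::pmap(thr, function(flag, lipid, direction, mmol_l, mg_dl) {
    trait <- trait_of[[lipid]]
    prs_col <- paste0(lipid, "_prs")
    g1 <- glance(fit_prs_logistic(cohort, flag, prs_col, covariates = c("age", "sex")))
    g2 <- glance(fit_prs_logistic(cohort, flag, prs_col,
                                  covariates = setdiff(default_covariates(trait), character(0))))
    keep <- lipid_model_filter(cohort) & !is.na(cohort[[prs_col]])
    bins <- bin_score(tibble(subject_id = cohort$subject_id[keep],
                             score = cohort[[prs_col]][keep]), k = 3)
    tert <- tidy(fit_bin_contrast(cohort, bins, flag, covariates = c("age", "sex")))
    top <- tert[nrow(tert), ]
    tibble(
      threshold = paste(toupper(lipid), direction, mmol_l, "mmol/L"),
      or_age_sex = g1$or_per_allele, or_age_sex_low = g1$conf.low,
      or_age_sex_high = g1$conf.high, p_age_sex = g1$p,
      or_full = g2$or_per_allele, or_full_low = g2$conf.low,
      or_full_high = g2$conf.high, p_full = g2$p,
      or_tertile = top$or, or_tertile_low = top$or.conf.low,
      or_tertile_high = top$or.conf.high, p_tertile = top$p.value,
      n_used = g2$n_used
    )
  })
  bind_rows(rows)
}
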