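#' ROC area under the curve with DeLong confidence interval
#'
#' AUC in the Mann-Whitney form (probability that a random case outscores
#' a random control, ties counted half), with a 95% CI from the DeLong
#' variance estimator. Computation is delegated to \pkg{pROC} with a
#' fixed direction (higher score = more case-like), so an
#' anti-discriminating score yields an AUC below 0.5 rather than being
#' silently flipped.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary labels (logical or 0/1); both classes required.
#' @return A one-row tibble: `auc`, `conf.low`, `conf.high`, `n_cases`,
#'   `n_controls`.
#' @examples
#' roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (length(unique(labels)) < 2) abort("both classes must be present")
  r <- pROC::roc(labels, scores, levels = c(0, 1), direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  ci <- tryCatch(suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong"))),
                 error = function(e) c(NA_real_, auc, NA_real_))
  if (anyNA(ci)) ci <- c(auc, auc, auc)  # degenerate variance (e.g. constant scores)
  tibble(auc = auc, conf.low = max(0, ci[1]), conf.high = min(1, ci[3]),
         n_cases = sum(labels == 1), n_controls = sum(labels == 0))
}

#' DeLong paired test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same subjects
#' (e.g. nested logistic models) with DeLong's paired test: a two-sided
#' normal test on the AUC difference using the DeLong covariance of the
#' paired empirical AUCs. If the paired variance is degenerate (for
#' instance when both prediction vectors are identical), the difference
#' is 0 by construction and `p = 1` is reported with `degenerate = TRUE`.
#'
#' @param pred_base,pred_augmented Prediction vectors on the same
#'   subjects, in the same order.
#' @param labels Binary labels.
#' @return A `roc_comparison` object with fields `auc_base`,
#'   `auc_augmented` (each a [roc_auc()] row), `auc_diff`, `p_value`,
#'   `degenerate`; `tidy()` gives a one-row tibble.
#' @export
delong_paired_test <- function(pred_base, pred_augmented, labels) {
  labels <- as.integer(labels)
  if (length(pred_base) != length(labels) || length(pred_augmented) != length(labels)) {
    abort("prediction vectors and labels must have equal length")
  }
  if (length(unique(labels)) < 2) abort("both classes must be present")
  r1 <- pROC::roc(labels, pred_base, levels = c(0, 1), direction = "<", quiet = TRUE)
  r2 <- pROC::roc(labels, pred_augmented, levels = c(0, 1), direction = "<", quiet = TRUE)
  auc1 <- roc_auc(pred_base, labels)
  auc2 <- roc_auc(pred_augmented, labels)
  degenerate <- isTRUE(all(pred_base == pred_augmented))
  p <- if (degenerate) 1 else tryCatch({
    tst <- suppressWarnings(pROC::roc.test(r1, r2, method = "delong", paired = TRUE))
    pv <- as.numeric(tst$p.value)
    if (!is.finite(pv)) { degenerate <- TRUE; 1 } else pv
  }, error = function(e) { degenerate <<- TRUE; 1 })
  structure(
    list(auc_base = auc1, auc_augmented = auc2,
         auc_diff = auc2$auc - auc1$auc, p_value = p, degenerate = degenerate,
         roc_base = r1, roc_augmented = r2),
    class = "roc_comparison"
  )
}

#' @describeIn delong_paired_test One-row summary of the paired comparison.
#' @param x A `roc_comparison` object.
#' @param ... Unused.
#' @export
tidy.roc_comparison <- function(x, ...) {
  tibble(
    auc_base = x$auc_base$auc,
    auc_base_low = x$auc_base$conf.low, auc_base_high = x$auc_base$conf.high,
    auc_augmented = x$auc_augmented$auc,
    auc_augmented_low = x$auc_augmented$conf.low,
    auc_augmented_high = x$auc_augmented$conf.high,
    auc_diff = x$auc_diff, p_value = x$p_value, degenerate = x$degenerate
  )
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("<roc_comparison> AUC %.3f (%.3f-%.3f) vs %.3f (%.3f-%.3f); p = %.3g\n",
              x$auc_base$auc, x$auc_base$conf.low, x$auc_base$conf.high,
              x$auc_augmented$auc, x$auc_augmented$conf.low,
              x$auc_augmented$conf.high, x$p_value))
  if (x$degenerate) cat("  (degenerate paired variance; p set to 1)\n")
  invisible(x)
}

#' Compare nested CAD risk models by ROC AUC
#'
#' Fits three in-sample logistic models of CAD -- the PRS with age and
#' sex (`age + sex + PRS`), the traditional cardiovascular risk factors
#' (`CRF`: age, sex, diabetes, hypertension, smoking), and `CRF + PRS`
#' -- on the common complete-case subjects, computes each model's AUC
#' with DeLong CIs, and tests whether adding the PRS to the CRF model
#' improves discrimination (DeLong paired test on the nested pair). No
#' cross-validation is applied; the AUCs are apparent (in-sample).
#'
#' @param cohort Cohort tibble with `cad`, the PRS column and the CRF
#'   covariates.
#' @param prs_col PRS column (default `"ldl_prs"`).
#' @return A `cad_roc_comparison` object: `aucs` (tibble, one row per
#'   model), `comparison` (the nested-pair `roc_comparison`), fitted
#'   models in `fits`. `tidy()` returns the per-model AUC table;
#'   `autoplot()` draws the three ROC curves.
#' @examples
#' sim <- simulate_cohort(sim_config(n_subjects = 400), seed = 11)
#' cmp <- compare_cad_models(cohort_table(sim))
#' tidy(cmp)
#' @export
compare_cad_models <- function(cohort, prs_col = "ldl_prs") {
  crf <- default_covariates("CAD")
  cols <- unique(c("cad", prs_col, crf))
  df <- model_frame(cohort, cols)
  if (length(unique(df$cad)) < 2) abort("both CAD classes must be present")
  f1 <- as.formula(paste("cad ~ age + sex +", backtick(prs_col)))
  f2 <- as.formula(paste("cad ~", paste(crf, collapse = " + ")))
  f3 <- as.formula(paste("cad ~", paste(c(crf, backtick(prs_col)), collapse = " + ")))
  fits <- list(
    prs_age_sex = glm(f1, data = df, family = binomial()),
    crf = glm(f2, data = df, family = binomial()),
    crf_prs = glm(f3, data = df, family = binomial())
  )
  preds <- lapply(fits, function(f) as.numeric(stats::fitted(f)))
  aucs <- purrr::imap(preds, function(p, nm) {
    bind_cols(tibble(model = nm), roc_auc(p, df$cad))
  }) %>% bind_rows()
  comparison <- delong_paired_test(preds$crf, preds$crf_prs, df$cad)
  structure(
    list(aucs = aucs, comparison = comparison, fits = fits,
         labels = as.integer(df$cad), preds = preds, n_used = nrow(df)),
    class = "cad_roc_comparison"
  )
}

#' @describeIn compare_cad_models Per-model AUC table plus the
#'   nested-pair p-value.
#' @param x A `cad_roc_comparison` object.
#' @param ... Unused.
#' @export
tidy.cad_roc_comparison <- function(x, ...) {
  x$aucs %>% mutate(p_vs_crf = ifelse(.data$model == "crf_prs",
                                      x$comparison$p_value, NA_real_))
}

#' @export
print.cad_roc_comparison <- function(x, ...) {
  cat("<cad_roc_comparison> n =", x$n_used, "\n")
  print(as.data.frame(tidy(x)), digits = 3, row.names = FALSE)
  invisible(x)
}

#' ROC coordinates of the fitted CAD models
#'
#' Sensitivity/specificity coordinates for each model curve, in a long
#' tibble suitable for plotting or TSV export.
#'
#' @param x A `cad_roc_comparison` object.
#' @return A tibble `model`, `specificity`, `sensitivity`.
#' @export
roc_coordinates <- function(x) {
  stopifnot(inherits(x, "cad_roc_comparison"))
  purrr::imap(x$preds, function(p, nm) {
    r <- pROC::roc(x$labels, p, levels = c(0, 1), direction = "<", quiet = TRUE)
    tibble(model = nm, specificity = r$specificities, sensitivity = r$sensitivities) %>%
      arrange(dplyr::desc(.data$specificity))
  }) %>% bind_rows()
}

#' @describeIn compare_cad_models ROC curves of the three CAD models.
#' @param object A `cad_roc_comparison` object.
#' @export
autoplot.cad_roc_comparison <- function(object, ...) {
  coords <- roc_coordinates(object)
  lab <- object$aucs %>%
    mutate(label = sprintf("%s: AUC %.3f (%.3f-%.3f)", .data$model, .data$auc,
                           .data$conf.low, .data$conf.high))
  coords <- coords %>% left_join(lab %>% select("model", "label"), by = "model")
  ggplot2::ggplot(coords, ggplot2::aes(x = 1 - .data$specificity,
                                       y = .data$sensitivity,
                                       colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity", colour = NULL,
                  title = "CAD discrimination of nested risk models") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom", legend.direction = "vertical")
}
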