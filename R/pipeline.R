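#' Write a simulated cohort to disk
#'
#' Writes the genotype TSV, phenotype CSV and generating-truth JSON for
#' a synthetic cohort, in the same dialects the readers accept. Two
#' calls with the same configuration and seed produce identical files.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_cohort <- function(cfg, seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_cohort(cfg, seed = seed)
  paths <- c(
    genotypes = file.path(out_dir, "genotypes.tsv"),
    phenotypes = file.path(out_dir, "phenotypes.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_genotypes(sim$genotypes, paths[["genotypes"]])
  pheno_out <- sim$phenotypes %>%
    mutate(sex = as.character(.data$sex),
           across(dplyr::where(is.logical), as.integer),
           across(dplyr::where(is.numeric), ~ round(.x, 6)))
  readr::write_csv(pheno_out, paths[["phenotypes"]], progress = FALSE, na = "")
  jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole chain on either real input files or a
#' simulated cohort: genotype QC, APOE calling, PRS construction, LDL
#' derivation and threshold categorization, linear and logistic
#' association tables, the CAD quartile contrast and the nested-model
#' ROC comparison. Each stage failure is re-raised with a stage tag.
#' All outputs are flat TSV files plus a plain-text run log recording
#' seeds, filter counts and the n used by each model.
#'
#' @param config A list (or path to a YAML/JSON file) with elements:
#'   * `inputs`: list with `genotypes` (TSV/VCF path) and `phenotypes`
#'     (CSV path), **or** `simulate`: list of [sim_config()] overrides
#'     (e.g. `n_subjects`); exactly one of the two must be present;
#'   * `seed`: integer, required when simulating;
#'   * `qc`: optional list with `min_call_rate`, `hwe_alpha`;
#'   * `missing_policy`: optional, `"mean_impute"` (default) or
#'     `"complete_case"`.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the main result tables.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.null(config$inputs) && is.null(config$simulate)) {
    abort("[config] either 'inputs' or 'simulate' must be present")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  log_add <- function(...) {
    line <- paste0(...)
    inform(line)
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)))
    })
  }
  panel <- ac_panel()
  defs <- default_score_definitions()

  if (!is.null(config$simulate)) {
    seed <- config$seed
    if (is.null(seed)) abort("[simulate] a seed is required")
    cfg <- stage("simulate", do.call(sim_config, config$simulate))
    sim <- stage("simulate", simulate_cohort(cfg, seed = seed))
    geno <- sim$genotypes
    pheno <- sim$phenotypes
    log_add("simulate: n = ", nrow(pheno), ", seed = ", seed)
  } else {
    geno <- stage("read_genotypes", read_genotypes(config$inputs$genotypes, panel))
    pheno <- stage("read_phenotypes", read_phenotypes(config$inputs$phenotypes))
    log_add("inputs: ", nrow(pheno), " subjects, ",
            ncol(geno) - 1, " variants")
  }

  qc_args <- config$qc %||% list()
  qc <- stage("qc", do.call(qc_panel, c(list(geno = geno, panel = panel,
                                             cohort = pheno), qc_args)))
  readr::write_tsv(qc, file.path(out_dir, "qc_report.tsv"), progress = FALSE)
  log_add("qc: ", sum(qc$pass), "/", nrow(qc), " variants pass")

  apoe <- stage("apoe", apoe_from_genotypes(geno))
  policy <- config$missing_policy %||% "mean_impute"
  cohort <- stage("score", {
    pheno %>%
      derive_clinical_flags() %>%
      derive_ldl() %>%
      categorize_lipids() %>%
      add_prs(geno, defs, missing_policy = policy)
  })
  cohort_out <- cohort %>%
    left_join(apoe %>% select("subject_id", "apoe", "ambiguous"), by = "subject_id")
  write_cohort(cohort_out, file.path(out_dir, "cohort.tsv"))
  n_ht_missing <- sum(is.na(cohort$hypertension))
  if (n_ht_missing > 0) {
    log_add("flags: ", n_ht_missing,
            " subject(s) with undeterminable hypertension (dropped from models using it)")
  }
  log_add("score: missing_policy = ", policy)

  lin <- stage("associate", association_table_linear(cohort))
  readr::write_tsv(lin, file.path(out_dir, "linear_associations.tsv"), progress = FALSE)
  n_excluded <- sum(!lipid_model_filter(cohort))
  log_add("associate: ", n_excluded,
          " subject(s) on lipid-lowering therapy and/or with CAD excluded from lipid-level models")
  log_add("associate: linear n_used = ", paste(lin$n_used, collapse = ", "))

  logi <- stage("associate", association_table_logistic(cohort))
  readr::write_tsv(logi, file.path(out_dir, "logistic_associations.tsv"), progress = FALSE)

  quart <- stage("associate", {
    keep <- !is.na(cohort$ldl_prs)
    bins <- bin_score(tibble(subject_id = cohort$subject_id[keep],
                             score = cohort$ldl_prs[keep]), k = 4)
    tidy(fit_bin_contrast(cohort, bins, "cad",
                          covariates = default_covariates("CAD")))
  })
  readr::write_tsv(quart, file.path(out_dir, "cad_quartile_or.tsv"), progress = FALSE)

  roc <- stage("discriminate", compare_cad_models(cohort))
  readr::write_tsv(tidy(roc), file.path(out_dir, "cad_roc_auc.tsv"), progress = FALSE)
  readr::write_tsv(roc_coordinates(roc), file.path(out_dir, "cad_roc_coordinates.tsv"),
                   progress = FALSE)
  readr::write_tsv(tidy(roc$comparison), file.path(out_dir, "cad_roc_comparison.tsv"),
                   progress = FALSE)
  log_add("discriminate: n_used = ", roc$n_used,
          ", delong p = ", signif(roc$comparison$p_value, 3))

  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(list(qc = qc, cohort = cohort, linear = lin, logistic = logi,
                 cad_quartiles = quart, roc = roc))
}

read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(paste0("unsupported config extension: '.", ext, "'"))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Forest-style plot of bin-contrast odds ratios
#'
#' Odds ratios (with 95% CIs) of each upper score bin against the
#' lowest, e.g. CAD risk across LDL-PRS quartiles.
#'
#' @param contrast A `prs_bin_contrast` object ([fit_bin_contrast()]).
#' @return A ggplot object.
#' @export
plot_bin_or <- function(contrast) {
  stopifnot(inherits(contrast, "prs_bin_contrast"))
  d <- tidy(contrast) %>%
    mutate(bin = sub("_vs_bin1$", "", .data$contrast)) %>%
    bind_rows(tibble(contrast = "bin1 (ref)", or = 1, or.conf.low = NA,
                     or.conf.high = NA, p.value = NA, n_used = NA, bin = "bin1")) %>%
    arrange(.data$bin)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$or)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$or.conf.low,
                                          ymax = .data$or.conf.high)) +
    ggplot2::labs(x = "Score bin (lowest = reference)", y = "Odds ratio (95% CI)") +
    ggplot2::theme_minimal()
}
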