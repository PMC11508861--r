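#' Read a genotype table (TSV or VCF) oriented to risk alleles
#'
#' Reads per-subject genotypes at the panel SNPs and returns risk-allele
#' dosages. Two formats are accepted:
#'
#' * **TSV**: a `subject_id` column plus one column per rsid. Each genotype
#'   cell is either an unordered allele pair (`"CT"`, `"C/T"` and `"C|T"`
#'   are equivalent) or an integer risk-allele dosage in `{0, 1, 2}`;
#'   the encoding is auto-detected per column. `"."` or an empty cell is a
#'   missing call.
#' * **VCF** (`.vcf`): variants are matched to the panel by the `ID` field
#'   only; `GT` genotypes are oriented so the returned dosage counts the
#'   panel's risk allele whether it is REF or ALT.
#'
#' @param path Path to the genotype file.
#' @param panel Variant panel (see [ac_panel()]); defines risk/other
#'   alleles and which columns/records are read.
#' @return A tibble with `subject_id` and one integer dosage column per
#'   panel rsid present in the file (`NA` = missing call).
#' @export
read_genotypes <- function(path, panel = ac_panel()) {
  validate_panel(panel)
  if (tolower(tools::file_ext(path)) == "vcf") {
    return(read_genotypes_vcf(path, panel))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"subject_id" %in% names(raw)) {
    abort("genotype TSV must have a 'subject_id' column")
  }
  rsids <- setdiff(names(raw), "subject_id")
  unknown <- setdiff(rsids, panel$rsid)
  if (length(unknown) > 0) {
    abort(paste0("unknown rsid column(s) in genotype file: ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(raw$subject_id)) abort("duplicate subject id in genotype file")
  out <- tibble(subject_id = raw$subject_id)
  for (rs in rsids) {
    row <- panel[panel$rsid == rs, ]
    out[[rs]] <- parse_genotype_column(raw[[rs]], rs, row$risk_allele, row$other_allele)
  }
  out
}

# One TSV genotype column -> integer risk-allele dosages.
# Dosage vs allele-pair encoding is auto-detected from the non-missing values.
parse_genotype_column <- function(x, rsid, risk, other) {
  x <- trimws(x)
  x[x %in% c(".", "", "NA")] <- NA_character_
  obs <- x[!is.na(x)]
  if (length(obs) == 0) return(rep(NA_integer_, length(x)))
  if (all(grepl("^[0-2]$", obs))) {
    return(suppressWarnings(as.integer(x)))
  }
  alleles <- gsub("[/|]", "", toupper(x))
  bad <- !is.na(alleles) & !grepl("^[ACGT]{2}$", alleles)
  if (any(bad)) {
    abort(paste0("unparseable genotype '", x[which(bad)[1]], "' at ", rsid))
  }
  a1 <- substr(alleles, 1, 1)
  a2 <- substr(alleles, 2, 2)
  known <- c(risk, other)
  bad_allele <- (!is.na(a1) & !a1 %in% known) | (!is.na(a2) & !a2 %in% known)
  if (any(bad_allele)) {
    abort(paste0("allele not in {", risk, ",", other, "} at ", rsid,
                 ": '", x[which(bad_allele)[1]], "'"))
  }
  as.integer((a1 == risk) + (a2 == risk))
}

read_genotypes_vcf <- function(path, panel) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ids <- vcfR::getID(v)
  keep <- which(ids %in% panel$rsid)
  if (length(keep) == 0) abort("no panel rsids found in VCF ID column")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fix <- vcfR::getFIX(v)[keep, , drop = FALSE]
  subjects <- colnames(gt)
  if (anyDuplicated(subjects)) abort("duplicate subject id in VCF")
  out <- tibble(subject_id = subjects)
  for (i in seq_along(keep)) {
    rs <- fix[i, "ID"]
    row <- panel[panel$rsid == rs, ]
    ref <- unname(toupper(fix[i, "REF"]))
    alt <- unname(toupper(fix[i, "ALT"]))
    if (!setequal(c(ref, alt), c(row$risk_allele, row$other_allele))) {
      abort(paste0("VCF REF/ALT (", ref, "/", alt, ") do not match panel alleles at ", rs))
    }
    g <- gt[i, ]
    alt_dose <- vapply(strsplit(ifelse(is.na(g), "", g), "[/|]"), function(al) {
      al <- al[al != "."]
      if (length(al) == 0) return(NA_integer_)
      sum(as.integer(al) > 0L)
    }, integer(1))
    out[[rs]] <- unname(if (alt == row$risk_allele) alt_dose else 2L - alt_dose)
  }
  out
}

#' Write a genotype dosage table as TSV
#'
#' Writes risk-allele dosages with `"."` for missing calls; the file
#' round-trips exactly through [read_genotypes()].
#'
#' @param geno Genotype tibble as returned by [read_genotypes()] or
#'   [simulate_genotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  out <- geno
  for (rs in setdiff(names(out), "subject_id")) {
    out[[rs]] <- ifelse(is.na(out[[rs]]), ".", as.character(out[[rs]]))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Reads the per-subject phenotype CSV. Expected columns (any order;
#' missing optional columns are added as `NA`): `subject_id`, `age`
#' (years), `sex` (`male`/`female`, case-insensitive), `bmi` (kg/m2),
#' `sbp`, `dbp` (mmHg), `tc`, `hdl`, `tg`, optionally `ldl` (all mmol/L),
#' `apob` (g/L), and 0/1 or TRUE/FALSE flags `on_antihypertensive`,
#' `on_lipid_lowering`, `diabetes_history`, `smoker_current`,
#' `alcohol_regular`, `cad`.
#'
#' @param path Path to the CSV file.
#' @return A tibble with typed columns; invalid values (negative lipids,
#'   non-positive age or BMI, unknown sex codes) raise an error.
#' @export
read_phenotypes <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"subject_id" %in% names(raw)) abort("phenotype CSV must have a 'subject_id' column")
  if (anyDuplicated(raw$subject_id)) abort("duplicate subject id in phenotype file")
  num_cols <- c("age", "bmi", "sbp", "dbp", "tc", "hdl", "tg", "ldl", "apob")
  flag_cols <- c("on_antihypertensive", "on_lipid_lowering", "diabetes_history",
                 "smoker_current", "alcohol_regular", "cad")
  out <- tibble(subject_id = raw$subject_id)
  out$sex <- if ("sex" %in% names(raw)) parse_sex(raw$sex) else factor(NA, levels = c("male", "female"))
  for (col in num_cols) {
    out[[col]] <- if (col %in% names(raw)) readr::parse_double(dplyr::na_if(raw[[col]], "")) else NA_real_
  }
  for (col in flag_cols) {
    out[[col]] <- if (col %in% names(raw)) parse_flag(raw[[col]]) else NA
  }
  if (any(out$age <= 0, na.rm = TRUE)) abort("age must be positive")
  if (any(out$bmi <= 0, na.rm = TRUE)) abort("bmi must be positive")
  lipids <- c("tc", "hdl", "tg", "ldl", "apob")
  for (col in lipids) {
    if (any(out[[col]] < 0, na.rm = TRUE)) abort(paste0(col, " must be non-negative"))
  }
  out
}

parse_sex <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("", ".", "na")] <- NA_character_
  x[x %in% c("m", "male")] <- "male"
  x[x %in% c("f", "female")] <- "female"
  bad <- !is.na(x) & !x %in% c("male", "female")
  if (any(bad)) abort(paste0("unknown sex code: '", x[which(bad)[1]], "'"))
  factor(x, levels = c("male", "female"))
}

parse_flag <- function(x) {
  x <- tolower(trimws(x))
  x[x %in% c("", ".", "na")] <- NA_character_
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "t", "yes")] <- TRUE
  out[x %in% c("0", "false", "f", "no")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) abort(paste0("unparseable flag value: '", x[which(bad)[1]], "'"))
  out
}

#' Write the harmonized cohort table as TSV
#'
#' @param cohort A cohort tibble (phenotypes plus any derived columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_tsv(cohort, path, progress = FALSE)
  invisible(path)
}
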