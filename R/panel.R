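#' The default 13-SNP lipid variant panel
#'
#' Returns the bundled panel of 13 lipid-associated SNPs used to build the
#' three unweighted polygenic risk scores: five LDL-raising variants
#' (including the two APOE SNPs rs429358 and rs7412), four HDL-lowering
#' variants and five TG-raising variants (rs3916027 contributes to both the
#' HDL and TG scores). Risk/other alleles, per-variant trait membership,
#' risk-allele frequencies in the Afro-Caribbean study population
#' (`raf_ac`, computed among CAD-free subjects) and published
#' European-ancestry frequencies and per-allele effects (`raf_pea`,
#' `beta_pea`, mmol/L) are carried along for QC reporting and simulation
#' defaults.
#'
#' @return A tibble with one row per variant and columns `rsid`, `gene`,
#'   `chr`, `risk_allele`, `other_allele`, `traits` (list-column of
#'   character vectors, subset of `"LDL"`, `"HDL"`, `"TG"`), `raf_ac`,
#'   `raf_pea`, `beta_pea`.
#' @examples
#' ac_panel()
#' @export
ac_panel <- function() {
  panel <- tibble::tribble(
    ~rsid,        ~gene,           ~chr, ~risk_allele, ~other_allele, ~traits,             ~raf_ac, ~raf_pea, ~beta_pea,
    "rs12916",    "HMGCR",         "5",  "C", "T", list("LDL"),         0.24, 0.38,  0.02,
    "rs1529729",  "SMARCA4",       "19", "C", "T", list("LDL"),         0.29, 0.45,  0.09,
    "rs599839",   "SORT1",         "1",  "A", "G", list("LDL"),         0.23, 0.77,  0.14,
    "rs429358",   "APOE112",       "19", "C", "T", list("LDL"),         0.24, 0.19,  0.24,
    "rs7412",     "APOE158",       "19", "C", "T", list("LDL"),         0.91, 0.96,  0.49,
    "rs301",      "LPL",           "8",  "C", "T", list("HDL"),         0.29, 0.75, -0.04,
    "rs3916027",  "SLC18A1/LPL",   "8",  "G", "A", list(c("HDL", "TG")), 0.59, 0.73, -0.04,
    "rs17231506", "CETP",          "16", "C", "T", list("HDL"),         0.73, 0.68, -0.07,
    "rs708272",   "CETP",          "16", "C", "T", list("HDL"),         0.76, 0.57, -0.06,
    "rs1260326",  "GCKR",          "2",  "T", "C", list("TG"),          0.16, 0.41,  0.10,
    "rs17145713", "BAZ1B",         "7",  "C", "T", list("TG"),          0.69, 0.80,  0.09,
    "rs328",      "LPL",           "8",  "C", "G", list("TG"),          0.94, 0.89,  0.11,
    "rs17108993", "RBP4",          "10", "G", "T", list("TG"),          0.16, 0.03,  0.14
  )
  panel$traits <- lapply(panel$traits, unlist)
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  required <- c("rsid", "risk_allele", "other_allele", "traits", "raf_ac")
  missing_cols <- setdiff(required, names(panel))
  if (length(missing_cols) > 0) {
    abort(paste0("panel is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(panel$rsid)) abort("panel rsids must be distinct")
  if (any(panel$risk_allele == panel$other_allele)) {
    abort("risk and other allele must differ for every variant")
  }
  if (any(panel$raf_ac < 0 | panel$raf_ac > 1)) abort("raf_ac must lie in [0, 1]")
  if (any(lengths(panel$traits) == 0)) abort("every variant must belong to at least one trait")
  bad <- setdiff(unlist(panel$traits), c("LDL", "HDL", "TG"))
  if (length(bad) > 0) abort(paste0("unknown trait(s): ", paste(bad, collapse = ", ")))
  invisible(panel)
}

#' Default score definitions for the three lipid PRSs
#'
#' The LDL score sums risk alleles over rs12916, rs1529729, rs599839,
#' rs429358 and rs7412; the HDL score over rs301, rs3916027, rs17231506 and
#' rs708272 (HDL-*lowering* alleles, so a higher score predicts lower HDL);
#' the TG score over rs1260326, rs17145713, rs3916027, rs328 and
#' rs17108993 plus the APOE epsilon2 haplotype dosage.
#'
#' @return A tibble with columns `trait`, `members` (list-column of rsids)
#'   and `include_apoe_e2` (logical; `TRUE` only for TG).
#' @examples
#' default_score_definitions()
#' @export
default_score_definitions <- function() {
  tibble(
    trait = c("LDL", "HDL", "TG"),
    members = list(
      c("rs12916", "rs1529729", "rs599839", "rs429358", "rs7412"),
      c("rs301", "rs3916027", "rs17231506", "rs708272"),
      c("rs1260326", "rs17145713", "rs3916027", "rs328", "rs17108993")
    ),
    include_apoe_e2 = c(FALSE, FALSE, TRUE)
  )
}

#' Read a score-definition configuration file
#'
#' Reads a YAML or JSON file describing which panel variants feed each of
#' the three scores. The file holds one block per trait, e.g.
#' ```yaml
#' LDL:
#'   members: [rs12916, rs1529729, rs599839, rs429358, rs7412]
#' TG:
#'   members: [rs1260326, rs17145713, rs3916027, rs328, rs17108993]
#'   include_apoe_e2: true
#' ```
#' A TG block that omits `include_apoe_e2` defaults it to `TRUE`
#' (the epsilon2 dosage is part of the standard TG score); other traits
#' default to `FALSE`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param panel Variant panel used to validate member rsids.
#' @return A tibble in the shape of [default_score_definitions()].
#' @export
read_score_config <- function(path, panel = ac_panel()) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(paste0("unsupported score config extension: '.", ext, "' (use yaml or json)"))
  )
  if (length(cfg) == 0) abort("score config is empty")
  defs <- purrr::imap(cfg, function(block, trait) {
    if (!trait %in% c("LDL", "HDL", "TG")) {
      abort(paste0("unknown trait '", trait, "' in score config"))
    }
    members <- unlist(block$members)
    if (length(members) == 0) {
      abort(paste0("trait '", trait, "' has an empty member list"))
    }
    unknown <- setdiff(members, panel$rsid)
    if (length(unknown) > 0) {
      abort(paste0("trait '", trait, "' references rsids absent from the panel: ",
                   paste(unknown, collapse = ", ")))
    }
    include_e2 <- block$include_apoe_e2
    if (is.null(include_e2)) include_e2 <- identical(trait, "TG")
    tibble(trait = trait, members = list(members),
           include_apoe_e2 = isTRUE(include_e2))
  })
  bind_rows(defs)
}
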