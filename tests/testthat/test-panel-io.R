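test_that("bundled panel has the 13 variants with their printed alleles", {
  panel <- ac_panel()
  expect_equal(nrow(panel), 13)
  expect_equal(anyDuplicated(panel$rsid), 0)
  expect_true(all(panel$risk_allele != panel$other_allele))
  expect_true(all(panel$raf_ac >= 0 & panel$raf_ac <= 1))
  expect_true(all(lengths(panel$traits) >= 1))
  # spot-check orientation of key variants
  expect_equal(panel$risk_allele[panel$rsid == "rs12916"], "C")
  expect_equal(panel$risk_allele[panel$rsid == "rs7412"], "C")
  expect_equal(panel$raf_ac[panel$rsid == "rs328"], 0.94)
  expect_setequal(panel$traits[panel$rsid == "rs3916027"][[1]], c("HDL", "TG"))
})

test_that("default score definitions carry 5/4/5(+e2) members", {
  defs <- default_score_definitions()
  expect_equal(lengths(defs$members), c(5, 4, 5))
  expect_equal(defs$include_apoe_e2, c(FALSE, FALSE, TRUE))
  expect_true(all(unlist(defs$members) %in% ac_panel()$rsid))
})

test_that("score config reading validates and defaults the APOE flag", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "LDL:",
    "  members: [rs12916, rs1529729, rs599839, rs429358, rs7412]",
    "TG:",
    "  members: [rs1260326, rs17145713, rs3916027, rs328, rs17108993]"
  ), path)
  defs <- read_score_config(path)
  expect_equal(nrow(defs), 2)
  # TG block without the flag defaults to including the epsilon2 dosage
  expect_true(defs$include_apoe_e2[defs$trait == "TG"])
  expect_false(defs$include_apoe_e2[defs$trait == "LDL"])

  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("LDL:", "  members: []"), bad)
  expect_error(read_score_config(bad), "empty member list")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("LDL:", "  members: [rs000001]"), bad2)
  expect_error(read_score_config(bad2), "absent from the panel")
  bad3 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("VLDL:", "  members: [rs12916]"), bad3)
  expect_error(read_score_config(bad3), "unknown trait")
})

test_that("bundled score config file matches the in-code defaults", {
  cfgfile <- system.file("extdata", "score_config.yaml", package = "lipidprs")
  skip_if(cfgfile == "", "extdata not installed")
  expect_equal(read_score_config(cfgfile), default_score_definitions())
})

test_that("genotype TSV parsing orients allele pairs to the risk allele", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "subject_id\trs12916\trs599839",
    "S1\tCT\t1",
    "S2\tTT\t2",
    "S3\t.\t0",
    "S4\tC/C\t."
  ), path)
  g <- read_genotypes(path)
  expect_equal(g$rs12916, c(1L, 0L, NA, 2L))    # risk allele C
  expect_equal(g$rs599839, c(1L, 2L, 0L, NA))   # dosage column auto-detected
})

test_that("genotype TSV parsing rejects malformed input", {
  write_file <- function(lines) {
    p <- tempfile(fileext = ".tsv")
    writeLines(lines, p)
    p
  }
  expect_error(read_genotypes(write_file(c("subject_id\trs9999", "S1\tCT"))),
               "unknown rsid")
  expect_error(read_genotypes(write_file(c("subject_id\trs12916", "S1\tCG"))),
               "allele not in")
  expect_error(read_genotypes(write_file(c("subject_id\trs12916", "S1\tCT", "S1\tTT"))),
               "duplicate subject")
  expect_error(read_genotypes(write_file(c("id\trs12916", "S1\tCT"))),
               "subject_id")
})

test_that("genotype write/read round-trips dosages and missingness", {
  set.seed(7)
  panel <- ac_panel()
  g <- tibble::tibble(subject_id = sprintf("S%02d", 1:20))
  for (rs in panel$rsid) {
    d <- sample(c(0:2, NA), 20, replace = TRUE)
    g[[rs]] <- as.integer(d)
  }
  path <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, path)
  expect_equal(read_genotypes(path), g)
})

test_that("VCF genotypes are oriented whether the risk allele is REF or ALT", {
  skip_if_not_installed("vcfR")
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
    "5\t100\trs12916\tT\tC\t.\tPASS\t.\tGT\t1/1\t0/1\t0/0",   # ALT is risk
    "1\t200\trs599839\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t./."   # REF is risk
  ), path)
  g <- read_genotypes(path)
  expect_equal(g$rs12916[match(c("S1", "S2", "S3"), g$subject_id)], c(2L, 1L, 0L))
  expect_equal(g$rs599839[match(c("S1", "S2", "S3"), g$subject_id)], c(2L, 1L, NA))
})

test_that("phenotype reading types columns and validates ranges", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "subject_id,age,sex,bmi,tc,hdl,tg,cad,smoker_current",
    "S1,54,Male,27.1,4.9,1.4,1.1,0,1",
    "S2,61,female,31.0,5.2,1.1,1.8,1,0",
    "S3,40,F,24.0,,1.3,0.9,0,"
  ), path)
  ph <- read_phenotypes(path)
  expect_equal(as.character(ph$sex), c("male", "female", "female"))
  expect_equal(ph$cad, c(FALSE, TRUE, FALSE))
  expect_true(is.na(ph$tc[3]) && is.na(ph$smoker_current[3]))
  expect_true(all(is.na(ph$sbp)))  # absent optional column added as NA

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,age,sex", "S1,-3,male"), bad)
  expect_error(read_phenotypes(bad), "age must be positive")
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("subject_id,sex", "S1,unknown"), bad2)
  expect_error(read_phenotypes(bad2), "unknown sex code")
})

test_that("clinical flags follow the guideline definitions and propagate missingness", {
  cohort <- tibble::tibble(
    subject_id = paste0("S", 1:6),
    bmi = c(30, 29.9, 31, NA, 25, 28),
    sbp = c(139, 150, NA, 120, NA, 141),
    dbp = c(89, 80, NA, 91, NA, 70),
    on_antihypertensive = c(FALSE, FALSE, TRUE, FALSE, FALSE, NA),
    on_lipid_lowering = c(FALSE, TRUE, FALSE, FALSE, NA, FALSE),
    diabetes_history = c(FALSE, TRUE, FALSE, NA, FALSE, TRUE),
    smoker_current = c(TRUE, FALSE, FALSE, FALSE, NA, TRUE),
    alcohol_regular = c(FALSE, FALSE, TRUE, FALSE, FALSE, NA)
  )
  f <- derive_clinical_flags(cohort)
  expect_equal(f$obesity, c(TRUE, FALSE, TRUE, NA, FALSE, FALSE))
  # sbp 139 / dbp 89 / no meds is below both thresholds
  expect_false(f$hypertension[1])
  expect_true(f$hypertension[2])          # sbp 150
  expect_true(f$hypertension[3])          # medication, BP absent
  expect_true(f$hypertension[4])          # dbp 91
  expect_true(is.na(f$hypertension[5]))   # no BP, no medication flag
  expect_true(f$hypertension[6])          # sbp 141 despite unknown meds
  expect_equal(f$diabetes, cohort$diabetes_history)
  expect_equal(f$hypercholesterolemia[1:3], c(FALSE, TRUE, FALSE))
  # idempotent on the derived table
  expect_equal(derive_clinical_flags(f)$hypertension, f$hypertension)
})
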