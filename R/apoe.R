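#' Call APOE epsilon genotypes from rs429358/rs7412 dosages
#'
#' Infers the APOE epsilon genotype from unphased C-allele dosages at
#' rs429358 and rs7412 under the standard haplotype map
#' `epsilon4 = (rs429358-C, rs7412-C)`, `epsilon3 = (T, C)`,
#' `epsilon2 = (T, T)`, with the rare epsilon1 haplotype (C, T) assumed
#' absent. Under that assumption the epsilon2 count is always
#' `2 - dosage_C(rs7412)` and the epsilon4 count is (at most) the
#' rs429358 C dosage. The rs429358/rs7412 double heterozygote `(1, 1)` is
#' resolved to epsilon2/epsilon4 and flagged `ambiguous` (the alternative
#' epsilon1/epsilon3 phase is excluded by assumption); dosage pairs that
#' cannot arise without epsilon1 (C dosage at rs429358 exceeding the C
#' dosage at rs7412) are also flagged and resolved with as many epsilon4
#' copies as the rs7412 C dosage allows, so the call is total on
#' `{0,1,2}^2` and never emits epsilon1.
#'
#' @param d429358_c,d7412_c Integer vectors of C-allele dosages in
#'   `{0, 1, 2}` (`NA` = missing; any missing input gives a missing call).
#' @return A tibble with columns `e2`, `e3`, `e4` (haplotype counts
#'   summing to 2), `apoe` (genotype label such as `"e3/e4"`) and
#'   `ambiguous`.
#' @examples
#' call_apoe(c(0, 0, 1), c(0, 2, 1))  # e2/e2, e3/e3, e2/e4 (ambiguous)
#' @export
call_apoe <- function(d429358_c, d7412_c) {
  if (length(d429358_c) != length(d7412_c)) {
    abort("rs429358 and rs7412 dosage vectors must have equal length")
  }
  check_dosage(d429358_c, "rs429358")
  check_dosage(d7412_c, "rs7412")
  e2 <- 2L - as.integer(d7412_c)
  e4 <- pmin(as.integer(d429358_c), as.integer(d7412_c))
  e3 <- 2L - e2 - e4
  ambiguous <- (d429358_c == 1L & d7412_c == 1L) | (d429358_c > d7412_c)
  miss <- is.na(d429358_c) | is.na(d7412_c)
  e2[miss] <- e3[miss] <- e4[miss] <- NA_integer_
  ambiguous[miss] <- NA
  label <- rep(NA_character_, length(e2))
  ok <- !miss
  label[ok] <- purrr::pmap_chr(list(e2[ok], e3[ok], e4[ok]), function(a, b, c) {
    paste(rep(c("e2", "e3", "e4"), times = c(a, b, c)), collapse = "/")
  })
  tibble(e2 = e2, e3 = e3, e4 = e4, apoe = label, ambiguous = ambiguous)
}

check_dosage <- function(x, what) {
  bad <- !is.na(x) & !x %in% c(0L, 1L, 2L)
  if (any(bad)) {
    abort(paste0("dosage at ", what, " outside {0,1,2}: ", x[which(bad)[1]]))
  }
  invisible(x)
}

#' Epsilon2 haplotype dosage for the TG score
#'
#' Counts epsilon2 haplotypes in a called APOE genotype. Under the
#' no-epsilon1 assumption this equals the T-allele dosage at rs7412 for
#' every rs429358/rs7412 dosage combination, including the ambiguous
#' double heterozygote (called epsilon2/epsilon4, one epsilon2 copy).
#'
#' @param apoe_calls Tibble from [call_apoe()].
#' @return Integer vector in `{0, 1, 2}` (`NA` where the call is missing).
#' @export
epsilon2_dosage <- function(apoe_calls) {
  if (!all(c("e2", "e3", "e4") %in% names(apoe_calls))) {
    abort("expected a tibble from call_apoe()")
  }
  apoe_calls$e2
}

#' Append APOE epsilon calls to a genotype table
#'
#' Convenience wrapper: calls [call_apoe()] on the rs429358/rs7412 dosage
#' columns of a genotype tibble and returns the calls keyed by subject.
#'
#' @param geno Genotype tibble containing `rs429358` and `rs7412` columns.
#' @return A tibble with `subject_id` plus the [call_apoe()] columns.
#' @export
apoe_from_genotypes <- function(geno) {
  for (rs in c("rs429358", "rs7412")) {
    if (!rs %in% names(geno)) abort(paste0("genotype table lacks ", rs))
  }
  bind_cols(geno["subject_id"], call_apoe(geno$rs429358, geno$rs7412))
}
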