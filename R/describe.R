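#' Descriptive cohort summary (overall and by sex)
#'
#' Standard baseline table: mean (SD) for continuous variables and
#' n (percent) for binary flags, overall and within each sex.
#' Percentages are computed over the non-missing denominator of each
#' variable within each column and rounded to one decimal.
#'
#' @param cohort Cohort tibble with `sex` and any of the summarised
#'   columns (`age`, `bmi`, `obesity`, `hypertension`, `diabetes`,
#'   `smoking`, `alcohol`, `cad`, `on_lipid_lowering`, `tc`, `ldl`,
#'   `hdl`, `tg`).
#' @return A tibble with one row per variable and columns `variable`,
#'   `stat` (`"mean_sd"` or `"n_pct"`), `all`, `male`, `female` plus the
#'   numeric components (`*_n`, `*_pct` or `*_mean`, `*_sd`).
#' @export
describe_cohort <- function(cohort) {
  cont <- intersect(c("age", "bmi", "tc", "ldl", "hdl", "tg"), names(cohort))
  bin <- intersect(c("obesity", "hypertension", "diabetes", "smoking",
                     "alcohol", "cad", "on_lipid_lowering"), names(cohort))
  groups <- list(all = rep(TRUE, nrow(cohort)),
                 male = cohort$sex %in% "male",
                 female = cohort$sex %in% "female")
  one_cont <- function(v) {
    row <- tibble(variable = v, stat = "mean_sd")
    for (g in names(groups)) {
      x <- cohort[[v]][groups[[g]]]
      row[[paste0(g, "_mean")]] <- mean(x, na.rm = TRUE)
      row[[paste0(g, "_sd")]] <- sd(x, na.rm = TRUE)
      row[[g]] <- sprintf("%.2f (%.2f)", row[[paste0(g, "_mean")]],
                          row[[paste0(g, "_sd")]])
    }
    row
  }
  one_bin <- function(v) {
    row <- tibble(variable = v, stat = "n_pct")
    for (g in names(groups)) {
      x <- cohort[[v]][groups[[g]]]
      n_yes <- sum(x %in% TRUE)
      denom <- sum(!is.na(x))
      pct <- binary_percent(n_yes, denom)
      row[[paste0(g, "_n")]] <- n_yes
      row[[paste0(g, "_pct")]] <- pct
      row[[g]] <- sprintf("%d (%.1f)", n_yes, pct)
    }
    row
  }
  bind_rows(purrr::map(cont, one_cont), purrr::map(bin, one_bin))
}

#' Percentage of a count over its denominator
#'
#' `100 * n / denom`, rounded to one decimal -- the convention used in
#' baseline characteristic tables.
#'
#' @param n Count.
#' @param denom Denominator (> 0).
#' @return Percentage rounded to one decimal place.
#' @examples
#' binary_percent(31, 357)  # female current smokers
#' @export
binary_percent <- function(n, denom) {
  if (any(denom <= 0)) abort("denominator must be positive")
  round(100 * n / denom, 1)
}
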