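#' Conventional MMSE total score
#'
#' Sums the 11 raw subitem scores, yielding the conventional 0-30 MMSE
#' total. Input rows are validated first.
#'
#' @param data A cohort tibble.
#' @param bank Item bank, by default [mmse_item_bank()].
#' @return `data` with an added integer column `total_score`.
#' @examples
#' cohort <- simulate_cohort(cohort_template(seed = 1))
#' dplyr::count(add_total_score(cohort), total_score) |> head()
#' @export
add_total_score <- function(data, bank = mmse_item_bank()) {
  validate_cohort(data, bank)
  data$total_score <- as.integer(rowSums(as.matrix(data[bank$item])))
  data
}

#' Classify by education-adjusted conventional cutoffs
#'
#' Applies the conventional education-adjusted total-score cutoffs
#' (illiterate <=17, primary <=20, secondary <=22, university <=23): a
#' subject whose total score is at or below the cutoff for their education
#' group screens as impaired.
#'
#' @param data A cohort tibble.
#' @param groups Education group table, by default [education_groups()].
#' @param bank Item bank, by default [mmse_item_bank()].
#' @return `data` with added columns `total_score` and
#'   `conventional_label` (`"impaired"` or `"normal"`).
#' @examples
#' cohort <- simulate_cohort(cohort_template(seed = 1))
#' classify_conventional(cohort) |>
#'   dplyr::count(education_group, label, conventional_label)
#' @export
classify_conventional <- function(data, groups = education_groups(),
                                  bank = mmse_item_bank()) {
  if (!"total_score" %in% names(data)) data <- add_total_score(data, bank)
  cutoff <- groups$conventional_cutoff[
    match(data$education_group, groups$group)
  ]
  if (anyNA(cutoff)) {
    rlang::abort("education_group not present in the supplied group table",
      class = "mmsedw_validation_error"
    )
  }
  data$conventional_label <-
    ifelse(data$total_score <= cutoff, "impaired", "normal")
  data
}
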