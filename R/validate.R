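# Validation of subject-level cohort tables.
#
# A cohort tibble has one row per subject with columns:
#   subject_id, education_group, label, (age, sex, provenance optional),
#   then the 11 item columns in canonical order.

cohort_meta_cols <- function() {
  c("subject_id", "education_group", "label", "age", "sex", "provenance")
}

#' Validate a cohort tibble
#'
#' Checks the structural invariants of a subject-level cohort: required
#' columns present, unique subject identifiers, known education groups,
#' case/control labels, and every item score an integer within
#' `[0, max_score]` for its subitem.
#'
#' @param data A cohort tibble (one row per subject).
#' @param bank Item bank tibble, by default [mmse_item_bank()].
#' @return `data`, invisibly, if valid; otherwise an error naming the
#'   offending column, row or item.
#' @export
validate_cohort <- function(data, bank = mmse_item_bank()) {
  required <- c("subject_id", "education_group", "label", bank$item)
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "cohort is missing required column(s): ",
      paste(missing, collapse = ", ")
    ), class = "mmsedw_format_error")
  }
  if (anyDuplicated(data$subject_id) > 0) {
    dup <- unique(data$subject_id[duplicated(data$subject_id)])
    rlang::abort(paste0(
      "duplicate subject_id value(s): ",
      paste(utils::head(dup, 5), collapse = ", ")
    ), class = "mmsedw_validation_error")
  }
  bad_grp <- which(!data$education_group %in% education_levels())
  if (length(bad_grp) > 0) {
    rlang::abort(sprintf(
      "unknown education_group %s in row %d",
      data$education_group[bad_grp[1]], bad_grp[1]
    ), class = "mmsedw_validation_error")
  }
  bad_lab <- which(!data$label %in% c("case", "control"))
  if (length(bad_lab) > 0) {
    rlang::abort(sprintf(
      "label must be 'case' or 'control' (row %d has %s)",
      bad_lab[1], data$label[bad_lab[1]]
    ), class = "mmsedw_validation_error")
  }
  for (i in seq_len(nrow(bank))) {
    it <- bank$item[i]
    v <- data[[it]]
    bad <- which(is.na(v) | v != as.integer(v) | v < 0 | v > bank$max_score[i])
    if (length(bad) > 0) {
      rlang::abort(sprintf(
        "item '%s' has missing or out-of-range score in row %d (max %d)",
        it, bad[1], bank$max_score[i]
      ), class = "mmsedw_validation_error")
    }
  }
  invisible(data)
}

# Internal: row-wise validity mask used by the lenient CSV reader.
# Returns a list(ok = logical, reason = character) without aborting.
cohort_row_status <- function(data, bank = mmse_item_bank()) {
  n <- nrow(data)
  reason <- rep(NA_character_, n)
  scores <- as.matrix(data[bank$item])
  suppressWarnings(storage.mode(scores) <- "double")
  miss <- rowSums(is.na(scores)) > 0
  reason[miss] <- "missing"
  rng <- !miss & (
    rowSums(scores < 0) > 0 |
      rowSums(sweep(scores, 2, bank$max_score, `>`)) > 0 |
      rowSums(scores != round(scores)) > 0
  )
  reason[rng] <- "out_of_range"
  bad_grp <- is.na(reason) & !data$education_group %in% education_levels()
  reason[bad_grp] <- "unknown_group"
  bad_lab <- is.na(reason) & !data$label %in% c("case", "control")
  reason[bad_lab] <- "bad_label"
  list(ok = is.na(reason), reason = reason)
}
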