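#' Weighted diagnostic score
#'
#' Computes each subject's weighted diagnostic score
#' `S = sum_i v_i * w_i`, normalised to the common 0-60 scale
#' (`raw * 60 / max_raw`), using the weight scheme of the subject's
#' education group.
#'
#' @param data A cohort tibble.
#' @param scheme A weight-scheme tibble covering every education group
#'   present in `data`; defaults to the packaged published schemes.
#' @param bank Item bank, by default [mmse_item_bank()].
#' @return `data` with added numeric columns `weighted_raw` and
#'   `weighted_score` (the normalised S).
#' @examples
#' cohort <- simulate_cohort(cohort_template(seed = 1))
#' add_weighted_score(cohort) |>
#'   dplyr::summarise(mean(weighted_score), .by = c(education_group, label))
#' @export
add_weighted_score <- function(data, scheme = published_weights(),
                               bank = mmse_item_bank()) {
  validate_cohort(data, bank)
  validate_weight_scheme(scheme, bank)
  absent <- setdiff(unique(data$education_group), unique(scheme$group))
  if (length(absent) > 0) {
    rlang::abort(sprintf(
      "no weight scheme for education group '%s'", absent[1]
    ), class = "mmsedw_validation_error")
  }
  summ <- scheme_summary(scheme, bank)
  wide_w <- tidyr::pivot_wider(scheme,
    names_from = "item", values_from = "weight"
  )
  wmat <- as.matrix(wide_w[bank$item])[
    match(data$education_group, wide_w$group), ,
    drop = FALSE
  ]
  raw <- rowSums(as.matrix(data[bank$item]) * wmat)
  max_raw <- summ$max_raw[match(data$education_group, summ$group)]
  data$weighted_raw <- raw
  data$weighted_score <- normalize_score(raw, max_raw)
  data
}

#' Classify by the weighted score and group threshold
#'
#' A subject screens as impaired when the normalised weighted score falls
#' strictly below the group threshold `T` (`S < T` impaired, `S >= T`
#' normal; thresholds 30/31/32/33 for illiterate through university).
#'
#' @param data A cohort tibble; `weighted_score` is computed if absent.
#' @param scheme Weight scheme used when the score must be computed.
#' @param groups Education group table carrying `weighted_threshold`.
#' @return `data` with an added `weighted_label` column.
#' @export
classify_weighted <- function(data, scheme = published_weights(),
                              groups = education_groups()) {
  if (!"weighted_score" %in% names(data)) {
    data <- add_weighted_score(data, scheme)
  }
  t_ <- groups$weighted_threshold[match(data$education_group, groups$group)]
  if (anyNA(t_)) {
    rlang::abort("education_group missing from group table",
      class = "mmsedw_validation_error"
    )
  }
  data$weighted_label <- ifelse(data$weighted_score < t_, "impaired", "normal")
  data
}
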