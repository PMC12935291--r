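# Weight schemes are long tibbles: one row per (group, item) with an
# integer weight in {1, 2, 3}. Per-group scale facts (max raw weighted sum,
# normalisation factor 60 / max_raw, threshold T) come from scheme_summary().

#' Validate a weight-scheme tibble
#'
#' A scheme tibble has columns `group`, `item`, `weight`; every group
#' covers all 11 subitems exactly once and every weight is an integer in
#' \{1, 2, 3\}.
#'
#' @param scheme A weight-scheme tibble.
#' @param bank Item bank, by default [mmse_item_bank()].
#' @return `scheme`, invisibly.
#' @export
validate_weight_scheme <- function(scheme, bank = mmse_item_bank()) {
  need <- c("group", "item", "weight")
  missing <- setdiff(need, names(scheme))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "weight scheme missing column(s): ", paste(missing, collapse = ", ")
    ), class = "mmsedw_format_error")
  }
  for (g in unique(scheme$group)) {
    sub <- scheme[scheme$group == g, ]
    gap <- setdiff(bank$item, sub$item)
    if (length(gap) > 0) {
      rlang::abort(sprintf(
        "weight scheme for group '%s' is missing item '%s'", g, gap[1]
      ), class = "mmsedw_validation_error")
    }
    if (anyDuplicated(sub$item) > 0) {
      rlang::abort(sprintf("duplicate item weights for group '%s'", g),
        class = "mmsedw_validation_error"
      )
    }
  }
  w <- scheme$weight
  bad <- which(is.na(w) | w != as.integer(w) | w < 1 | w > 3)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "weights must be integers in {1,2,3}; offending value %s for %s/%s",
      format(w[bad[1]]), scheme$group[bad[1]], scheme$item[bad[1]]
    ), class = "mmsedw_validation_error")
  }
  invisible(scheme)
}

#' Published education-specific weight schemes
#'
#' Returns the packaged education-specific integer item weights (with
#' spatial orientation uniformly weighted 3 in every group) together with
#' the group thresholds on the 60-point scale. These constants are shipped
#' as authoritative for weighted scoring; [derive_weights()] implements the
#' generic category-to-weight rule and is not claimed to regenerate them.
#'
#' @param group Optional single group name to subset to.
#' @return A weight-scheme tibble (`group`, `item`, `weight`).
#' @examples
#' scheme_summary(published_weights())
#' @export
published_weights <- function(group = NULL) {
  path <- system.file("extdata", "published_weights.json",
    package = "mmsedw", mustWork = TRUE
  )
  schemes <- read_weight_schemes(path)
  if (!is.null(group)) {
    stopifnot(group %in% schemes$group)
    schemes <- schemes[schemes$group == group, ]
  }
  schemes
}

#' Read weight schemes from JSON
#'
#' The JSON format is `{group: {item_id: weight, ...}, ...}` with an
#' optional `"thresholds"` block (ignored here; thresholds live in
#' [education_groups()]).
#'
#' @param path Path to a JSON weight-scheme document.
#' @param bank Item bank, by default [mmse_item_bank()].
#' @return A validated weight-scheme tibble.
#' @export
read_weight_schemes <- function(path, bank = mmse_item_bank()) {
  doc <- jsonlite::read_json(path)
  doc <- doc[setdiff(names(doc), "thresholds")]
  scheme <- purrr::imap(doc, function(w, g) {
    tibble::tibble(
      group = g,
      item = names(w),
      weight = as.integer(unlist(w))
    )
  }) |>
    purrr::list_rbind() |>
    dplyr::arrange(
      match(.data$group, education_levels()),
      match(.data$item, bank$item)
    )
  validate_weight_scheme(scheme, bank)
  scheme
}

#' Write weight schemes to JSON
#'
#' @param scheme A weight-scheme tibble.
#' @param path Destination path.
#' @param thresholds Optional named vector of group thresholds to embed.
#' @return `path`, invisibly.
#' @export
write_weight_schemes <- function(scheme, path, thresholds = NULL) {
  validate_weight_scheme(scheme)
  doc <- split(scheme, scheme$group)[unique(scheme$group)] |>
    purrr::map(function(s) as.list(stats::setNames(s$weight, s$item)))
  if (!is.null(thresholds)) doc$thresholds <- as.list(thresholds)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Per-group scale facts of a weight scheme
#'
#' For each group: the maximum attainable raw weighted sum
#' `max_raw = sum(max_score_i * w_i)`, the normalisation factor
#' `60 / max_raw`, and the diagnostic threshold `T` on the 60-point scale.
#'
#' @param scheme A weight-scheme tibble.
#' @param bank Item bank, by default [mmse_item_bank()].
#' @param groups Education group table, by default [education_groups()].
#' @return A tibble with columns `group`, `max_raw`, `norm_factor`,
#'   `weighted_threshold`.
#' @export
scheme_summary <- function(scheme, bank = mmse_item_bank(),
                           groups = education_groups()) {
  validate_weight_scheme(scheme, bank)
  scheme |>
    dplyr::left_join(bank[c("item", "max_score")], by = "item") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      max_raw = sum(.data$max_score * .data$weight),
      .groups = "drop"
    ) |>
    dplyr::mutate(norm_factor = 60 / .data$max_raw) |>
    dplyr::left_join(
      groups[c("group", "weighted_threshold")],
      by = "group"
    ) |>
    dplyr::arrange(match(.data$group, education_levels()))
}

#' Derive integer item weights from an ablation result
#'
#' Maps each item's contribution category to a weight: critical items
#' (removal costs more than 1 accuracy point) get weight 3, neutral items
#' 2, interference items (removal gains more than 0.5 points) 1. The rule
#' is a monotone step function of the contribution statistic: a more
#' helpful item never gets a smaller weight.
#'
#' @param ablation An ablation result from [ablate_items()], or any tibble
#'   with columns `group`, `item` and `category`.
#' @param rule Named integer vector mapping category to weight.
#' @return A validated weight-scheme tibble.
#' @seealso [published_weights()] for the packaged authoritative schemes.
#' @export
derive_weights <- function(ablation,
                           rule = c(critical = 3L, neutral = 2L,
                                    interference = 1L)) {
  need <- c("group", "item", "category")
  missing <- setdiff(need, names(ablation))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "ablation result missing column(s): ", paste(missing, collapse = ", ")
    ), class = "mmsedw_format_error")
  }
  gap <- setdiff(item_ids(), ablation$item)
  if (length(gap) > 0) {
    rlang::abort(sprintf(
      "ablation result incomplete: no entry for item '%s'", gap[1]
    ), class = "mmsedw_validation_error")
  }
  scheme <- tibble::tibble(
    group = ablation$group,
    item = ablation$item,
    weight = unname(rule[ablation$category])
  )
  validate_weight_scheme(scheme)
  scheme
}

#' Normalise a raw weighted sum to the common 60-point scale
#'
#' Per-group linear rescaling `raw * 60 / max_raw`, the unique linear map
#' under which a maximal response scores exactly 60 in every group even
#' though raw maxima differ. Values are kept real (not rounded) so that
#' rank-based statistics are unaffected.
#'
#' @param raw Numeric vector of raw weighted sums.
#' @param max_raw Maximum attainable raw weighted sum for the group
#'   (see [scheme_summary()]).
#' @return Numeric vector on the 0-60 scale.
#' @export
normalize_score <- function(raw, max_raw) {
  stopifnot(max_raw > 0)
  if (any(raw < 0 | raw > max_raw)) {
    rlang::abort("raw weighted sum outside [0, max_raw]",
      class = "mmsedw_validation_error"
    )
  }
  raw * 60 / max_raw
}
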