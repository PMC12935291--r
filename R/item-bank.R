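#' The canonical MMSE item bank
#'
#' The Mini-Mental State Examination partitions into 11 scored subitems
#' spanning orientation, memory, attention/calculation, language and
#' visuospatial construction. The point allocation follows the standard
#' Folstein structure (5, 5, 3, 5, 3, 2, 1, 3, 1, 1, 1), which sums to the
#' familiar 30-point total. Item order is fixed and used throughout the
#' package: cohort CSV columns, weight schemes and contribution matrices all
#' follow it.
#'
#' "Execution ability" denotes the 3-point three-stage command;
#' "spatial structure" the 1-point intersecting-pentagon copy.
#'
#' @return A tibble with one row per subitem and columns `item` (canonical
#'   identifier), `label` (display label) and `max_score` (maximum raw
#'   points).
#' @examples
#' bank <- mmse_item_bank()
#' sum(bank$max_score) # 30
#' @export
mmse_item_bank <- function() {
  tibble::tibble(
    item = c(
      "time_orientation", "space_orientation", "immediate_memory",
      "attention_calculation", "delayed_memory", "naming", "repetition",
      "execution_ability", "reading", "writing", "spatial_structure"
    ),
    label = c(
      "Orientation (time)", "Orientation (space)", "Memory (immediate)",
      "Attention and calculation", "Memory (delayed)", "Naming",
      "Repetition", "Execution ability", "Reading", "Writing",
      "Spatial structure"
    ),
    max_score = c(5L, 5L, 3L, 5L, 3L, 2L, 1L, 3L, 1L, 1L, 1L)
  )
}

#' Education strata with conventional cutoffs and weighted thresholds
#'
#' Subjects are stratified into four education groups. Each group carries a
#' conventional education-adjusted total-score cutoff (Chinese normative
#' standards: a total score at or below the cutoff screens as impaired) and
#' a threshold `T` on the normalised 60-point weighted scale (a weighted
#' score `S < T` screens as impaired).
#'
#' @return A tibble with columns `group`, `years_band`,
#'   `conventional_cutoff` and `weighted_threshold`, in fixed order
#'   illiterate, primary, secondary, university.
#' @examples
#' education_groups()
#' @export
education_groups <- function() {
  tibble::tibble(
    group = c("illiterate", "primary", "secondary", "university"),
    years_band = c("0 y", "<=6 y", "7-12 y", ">=13 y"),
    conventional_cutoff = c(17L, 20L, 22L, 23L),
    weighted_threshold = c(30L, 31L, 32L, 33L)
  )
}

#' @rdname education_groups
#' @format NULL
#' @usage NULL
#' @export
education_levels <- function() education_groups()$group

# Internal: item identifier vector in canonical order
item_ids <- function() mmse_item_bank()$item

#' Export item bank and group constants as JSON
#'
#' Writes the canonical item identifiers, maximum scores, conventional
#' cutoffs and weighted thresholds to a JSON document so that external
#' configurations can reference them bit-exactly.
#'
#' @param path File path to write to.
#' @return `path`, invisibly.
#' @export
write_mmse_constants <- function(path) {
  bank <- mmse_item_bank()
  grp <- education_groups()
  doc <- list(
    items = purrr::pmap(bank, function(item, label, max_score) {
      list(id = item, label = label, max_score = max_score)
    }),
    groups = purrr::pmap(grp, function(group, years_band,
                                       conventional_cutoff,
                                       weighted_threshold) {
      list(
        name = group, years_band = years_band,
        conventional_cutoff = conventional_cutoff,
        weighted_threshold = weighted_threshold
      )
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
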