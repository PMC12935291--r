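#' Read an item-level cohort CSV with exclusion accounting
#'
#' Reads a subject-level MMSE cohort from CSV. The header must name
#' `subject_id`, `education_group`, `label` and the 11 canonical item
#' columns; `age`, `sex` and `provenance` are optional. Rows with a missing
#' or unparseable item score are excluded and counted (mirroring a
#' quality-control flow in which invalid records are dropped, not fatal);
#' other per-row validation failures are excluded under their own reason.
#' In strict mode any invalid row aborts the read instead.
#'
#' @param path Path to a CSV file.
#' @param bank Item bank, by default [mmse_item_bank()].
#' @param strict If `TRUE`, abort on the first invalid row.
#' @return A cohort tibble of the retained rows, with the exclusion report
#'   attached as attribute `"exclusions"` (retrieve with
#'   [exclusion_report()]).
#' @seealso [write_cohort()], [exclusion_report()]
#' @export
read_cohort <- function(path, bank = mmse_item_bank(), strict = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(paste0("cohort file not found: ", path),
      class = "mmsedw_io_error"
    )
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("subject_id", "education_group", "label", bank$item)
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "malformed cohort header; missing column(s): ",
      paste(missing, collapse = ", ")
    ), class = "mmsedw_format_error")
  }
  for (it in bank$item) {
    raw[[it]] <- suppressWarnings(as.numeric(raw[[it]]))
  }
  if ("age" %in% names(raw)) {
    raw$age <- suppressWarnings(as.numeric(raw$age))
  }
  if (!"provenance" %in% names(raw)) raw$provenance <- "clinical"

  status <- cohort_row_status(raw, bank)
  if (strict && !all(status$ok)) {
    bad <- which(!status$ok)[1]
    rlang::abort(sprintf(
      "row %d failed validation (%s)", bad, status$reason[bad]
    ), class = "mmsedw_validation_error")
  }
  kept <- raw[status$ok, , drop = FALSE]
  for (it in bank$item) kept[[it]] <- as.integer(kept[[it]])

  other <- table(status$reason[!status$ok & status$reason != "missing"])
  report <- new_exclusion_report(
    n_input = nrow(raw),
    n_excluded_missing = sum(status$reason == "missing", na.rm = TRUE),
    n_excluded_other = stats::setNames(as.integer(other), names(other)),
    n_retained = nrow(kept)
  )
  kept <- kept[c(
    intersect(cohort_meta_cols(), names(kept)), bank$item
  )]
  validate_cohort(kept, bank)
  attr(kept, "exclusions") <- report
  kept
}

#' Write a cohort tibble to CSV
#'
#' Columns are emitted in the canonical order (`subject_id`,
#' `education_group`, `label`, `age`, `sex`, `provenance` when present,
#' then the 11 item columns). Reading the file back with [read_cohort()]
#' reproduces all fields exactly.
#'
#' @param data A valid cohort tibble.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(data, path) {
  validate_cohort(data)
  cols <- c(intersect(cohort_meta_cols(), names(data)), item_ids())
  readr::write_csv(data[cols], path, progress = FALSE)
  invisible(path)
}

new_exclusion_report <- function(n_input, n_excluded_missing,
                                 n_excluded_other, n_retained) {
  rep <- list(
    n_input = as.integer(n_input),
    n_excluded_missing = as.integer(n_excluded_missing),
    n_excluded_other = n_excluded_other,
    n_retained = as.integer(n_retained)
  )
  stopifnot(
    rep$n_input ==
      rep$n_retained + rep$n_excluded_missing + sum(rep$n_excluded_other)
  )
  structure(rep, class = "mmsedw_exclusions")
}

#' Exclusion report of a cohort read
#'
#' @param data A cohort tibble returned by [read_cohort()].
#' @return A list with `n_input`, `n_excluded_missing`, `n_excluded_other`
#'   (named counts by reason) and `n_retained`; the totals always
#'   reconcile.
#' @export
exclusion_report <- function(data) {
  rep <- attr(data, "exclusions")
  if (is.null(rep)) {
    rlang::abort("no exclusion report attached; was this read_cohort() output?")
  }
  rep
}

#' @export
print.mmsedw_exclusions <- function(x, ...) {
  cat(sprintf(
    "cohort read: %d input, %d retained, %d excluded (missing %d%s)\n",
    x$n_input, x$n_retained, x$n_input - x$n_retained,
    x$n_excluded_missing,
    if (length(x$n_excluded_other)) {
      paste0(", ", paste(names(x$n_excluded_other),
        x$n_excluded_other,
        sep = " ", collapse = ", "
      ))
    } else {
      ""
    }
  ))
  invisible(x)
}
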