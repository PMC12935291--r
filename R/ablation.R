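# Item-deletion contribution analysis. Each subitem is removed in turn and
# the cross-validated accuracy recomputed with the remaining 10 features,
# on the SAME fold assignment and with the SAME (C, gamma) as the baseline
# fit, so the contribution statistic reflects the feature's removal rather
# than resampling or search noise.

#' Contribution statistic from two accuracies
#'
#' `delta = post-deletion accuracy - baseline accuracy`, in percentage
#' points. Negative delta means the item helped (performance dropped when
#' it was removed); positive delta means it acted as noise.
#'
#' @param baseline,post Accuracies in percent, each in \[0, 100\].
#' @return Delta in percentage points.
#' @examples
#' delta_accuracy(85.71, 83.81) # -1.90
#' @export
delta_accuracy <- function(baseline, post) {
  stopifnot(
    all(baseline >= 0 & baseline <= 100),
    all(post >= 0 & post <= 100)
  )
  post - baseline
}

#' Categorise an item by its contribution statistic
#'
#' Critical items lose more than 1 accuracy point on removal
#' (`delta < -1.0`); interference items gain more than 0.5 points
#' (`delta > +0.5`); everything else — including exact boundary values —
#' is neutral.
#'
#' @param delta Numeric vector of contribution statistics (pp).
#' @return Character vector: `"critical"`, `"neutral"` or
#'   `"interference"`.
#' @examples
#' delta_category(c(-6.58, 0, 0.95))
#' @export
delta_category <- function(delta) {
  stopifnot(all(is.finite(delta)))
  dplyr::case_when(
    delta < -1.0 ~ "critical",
    delta > 0.5 ~ "interference",
    .default = "neutral"
  )
}

#' Item-deletion (ablation) analysis for one education group
#'
#' Computes the baseline cross-validated accuracy on all 11 items, then
#' removes each subitem in turn and retrains the SVM on the remaining 10
#' with identical folds and hyperparameters. Hyperparameters are frozen at
#' the supplied (or refitted) baseline optimum by default; set
#' `research_per_deletion = TRUE` to rerun the grid search for every
#' deletion instead.
#'
#' @param data A cohort tibble restricted to a single education group.
#' @param cv A [cv_config()].
#' @param fit Optional baseline `mmsedw_fit` (from [svm_grid_search()] on
#'   the same data/cv); computed when absent.
#' @param research_per_deletion If `TRUE`, redo the full grid search for
#'   each deletion rather than freezing (C, gamma).
#' @return An object of class `mmsedw_ablation`: a tibble with columns
#'   `group`, `item`, `post_accuracy` (%), `delta` (pp) and `category`,
#'   with the baseline accuracy, (C, gamma) and folds as attributes.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_template(seed = 1))
#' ill <- dplyr::filter(cohort, education_group == "illiterate")
#' abl <- ablate_items(ill, cv_config(seed = 1))
#' abl
#' }
#' @export
ablate_items <- function(data, cv = cv_config(), fit = NULL,
                         research_per_deletion = FALSE) {
  grp <- unique(data$education_group)
  if (length(grp) != 1) {
    rlang::abort("ablate_items expects a single education group",
      class = "mmsedw_validation_error"
    )
  }
  folds <- if (!is.null(fit)) fit$folds else stratified_folds(data, cv)
  if (is.null(fit)) fit <- svm_grid_search(data, cv, folds = folds)
  baseline <- fit$mean_accuracy

  out <- purrr::map(item_ids(), function(drop) {
    feats <- setdiff(item_ids(), drop)
    post <- if (research_per_deletion) {
      svm_grid_search(data, cv, folds = folds, features = feats)$mean_accuracy
    } else {
      cross_val_accuracy(data, fit$C, fit$gamma, cv,
        folds = folds, features = feats
      )$mean_accuracy
    }
    tibble::tibble(item = drop, post_accuracy = post)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      group = grp,
      delta = delta_accuracy(baseline, .data$post_accuracy),
      category = delta_category(.data$delta),
      .before = 1
    ) |>
    dplyr::relocate("group", "item", "post_accuracy", "delta", "category")
  structure(out,
    class = c("mmsedw_ablation", class(out)),
    baseline_accuracy = baseline, C = fit$C, gamma = fit$gamma,
    folds = folds
  )
}

#' Baseline accuracy of an ablation result
#'
#' @param x A `mmsedw_ablation`.
#' @return Baseline cross-validated accuracy in percent.
#' @export
baseline_accuracy <- function(x) {
  stopifnot(inherits(x, "mmsedw_ablation"))
  attr(x, "baseline_accuracy")
}

#' @export
print.mmsedw_ablation <- function(x, ...) {
  cat(sprintf(
    "Item-deletion analysis [%s]: baseline %.2f%% (C=%g, gamma=%g)\n",
    x$group[1], attr(x, "baseline_accuracy"), attr(x, "C"), attr(x, "gamma")
  ))
  NextMethod()
}

#' Tidy an ablation result
#'
#' @param x A `mmsedw_ablation`.
#' @param ... Unused.
#' @return A plain tibble with `group`, `item`, `baseline_accuracy`,
#'   `post_accuracy`, `delta` and `category`.
#' @export
tidy.mmsedw_ablation <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(
      baseline_accuracy = attr(x, "baseline_accuracy"),
      .after = "item"
    )
}

#' Cross-group contribution matrix
#'
#' Binds per-group ablation results into a wide group-by-item matrix of
#' contribution statistics (rows in fixed group order, columns in item
#' bank order), suitable for export or heat-mapping.
#'
#' @param results A list of `mmsedw_ablation` objects (any subset of the
#'   four groups; missing groups are omitted with a warning).
#' @param path Optional CSV path; when given the matrix is also written
#'   (first column `group`).
#' @return A tibble with column `group` then one column per item.
#' @export
contribution_matrix <- function(results, path = NULL) {
  if (length(results) == 0) rlang::abort("need at least one ablation result")
  long <- purrr::map(results, tibble::as_tibble) |> purrr::list_rbind()
  present <- unique(long$group)
  absent <- setdiff(education_levels(), present)
  if (length(absent) > 0) {
    rlang::warn(paste0(
      "contribution matrix missing group(s): ", paste(absent, collapse = ", ")
    ))
  }
  wide <- long |>
    dplyr::select("group", "item", "delta") |>
    tidyr::pivot_wider(names_from = "item", values_from = "delta") |>
    dplyr::arrange(match(.data$group, education_levels()))
  wide <- wide[c("group", intersect(item_ids(), names(wide)))]
  if (!is.null(path)) readr::write_csv(wide, path, progress = FALSE)
  wide
}

#' Plot an ablation profile
#'
#' Bar chart of the contribution statistic per subitem, coloured by
#' category; the critical (-1.0) and interference (+0.5) thresholds are
#' drawn as dashed lines.
#'
#' @param object A `mmsedw_ablation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.mmsedw_ablation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$item <- factor(df$item, levels = rev(item_ids()))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$delta, y = .data$item, fill = .data$category
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = c(-1, 0.5), linetype = "dashed") +
    ggplot2::labs(
      x = "Δ accuracy after deletion (pp)", y = NULL,
      title = sprintf(
        "Item contributions [%s], baseline %.2f%%",
        df$group[1], attr(object, "baseline_accuracy")
      )
    )
}

#' @export
ggplot2::autoplot
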