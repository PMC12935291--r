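# Diagnostic evaluation. Impairment is the positive class throughout:
# sensitivity is the detection rate among cases, specificity the pass rate
# among controls, and AUC is oriented so that lower diagnostic scores in
# cases give higher AUC.

#' Confusion-matrix metrics
#'
#' @param truth Character vector, `"case"` / `"control"`.
#' @param predicted Character vector, `"impaired"` / `"normal"`.
#' @return One-row tibble with counts `tp`, `fn`, `tn`, `fp` and
#'   `accuracy`, `sensitivity`, `specificity` in percent. With
#'   single-class truth the undefined rate is `NA` (flagged, not silent
#'   zero).
#' @examples
#' compute_metrics(
#'   c("case", "case", "case", "case", "control", "control", "control", "control"),
#'   c("impaired", "impaired", "impaired", "normal", "normal", "normal", "impaired", "impaired")
#' )
#' @export
compute_metrics <- function(truth, predicted) {
  stopifnot(
    length(truth) == length(predicted), length(truth) > 0,
    all(truth %in% c("case", "control")),
    all(predicted %in% c("impaired", "normal"))
  )
  tp <- sum(truth == "case" & predicted == "impaired")
  fn <- sum(truth == "case" & predicted == "normal")
  tn <- sum(truth == "control" & predicted == "normal")
  fp <- sum(truth == "control" & predicted == "impaired")
  tibble::tibble(
    tp = tp, fn = fn, tn = tn, fp = fp,
    accuracy = 100 * (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  )
}

#' Rank-based AUC (Mann-Whitney with midranks)
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic
#' with midranks for ties, oriented so that lower diagnostic scores in
#' cases yield higher AUC (impairment-positive). Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores Numeric diagnostic scores (lower = more impaired).
#' @param truth Character vector `"case"` / `"control"`.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, truth) {
  stopifnot(
    length(scores) == length(truth),
    all(truth %in% c("case", "control"))
  )
  n_case <- sum(truth == "case")
  n_ctrl <- sum(truth == "control")
  if (n_case == 0 || n_ctrl == 0) {
    rlang::abort("both classes required for AUC",
      class = "mmsedw_validation_error"
    )
  }
  r <- rank(scores, ties.method = "average")
  # P(score_control > score_case) + 0.5 P(tie)
  (sum(r[truth == "control"]) - n_ctrl * (n_ctrl + 1) / 2) /
    (n_case * n_ctrl)
}

#' Exact McNemar test on paired classifier correctness
#'
#' Exact binomial test on the discordant pairs (subjects one classifier
#' gets right and the other wrong), the standard paired comparison of two
#' classifiers evaluated on the same subjects.
#'
#' @param correct_before,correct_after Logical vectors of per-subject
#'   correctness under the two conditions.
#' @return Two-sided p-value; 1 when there are no discordant pairs.
#' @export
mcnemar_exact <- function(correct_before, correct_after) {
  stopifnot(length(correct_before) == length(correct_after))
  b <- sum(correct_before & !correct_after)
  c_ <- sum(!correct_before & correct_after)
  if (b + c_ == 0) {
    return(1)
  }
  stats::binom.test(b, b + c_, p = 0.5)$p.value
}

#' Bootstrap test for the accuracy difference
#'
#' Percentile bootstrap over subjects of the paired accuracy difference
#' (after - before); the p-value is the two-sided tail probability of the
#' resampled difference crossing zero.
#'
#' @inheritParams mcnemar_exact
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @return Two-sided p-value.
#' @export
bootstrap_accuracy_test <- function(correct_before, correct_after,
                                    n_boot = 2000, seed = 0L) {
  stopifnot(length(correct_before) == length(correct_after))
  n <- length(correct_before)
  with_preserved_seed(seed, {
    diffs <- purrr::map_dbl(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      mean(correct_after[idx]) - mean(correct_before[idx])
    })
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    min(1, p)
  })
}

#' Before/after diagnostic comparison for one education group
#'
#' "Before" applies the conventional education-adjusted cutoff to the
#' total score; "after" applies the group threshold `T` to the weighted
#' score `S`. Both are evaluated on the same subjects: accuracy,
#' sensitivity, specificity (percent), rank-based AUC (total score before,
#' `S` after), the accuracy improvement in percentage points and the exact
#' McNemar p-value for the paired comparison. `before = "svm"` instead
#' evaluates the cross-validated baseline SVM predictions as the "before"
#' condition.
#'
#' @param data A cohort tibble restricted to one education group.
#' @param scheme Weight scheme; defaults to the packaged published schemes.
#' @param groups Education group table.
#' @param before `"cutoff"` (default) or `"svm"`.
#' @param cv A [cv_config()], used only when `before = "svm"`.
#' @param test `"mcnemar"` (default, exact) or `"bootstrap"`.
#' @return An object of class `mmsedw_eval`: a two-row tibble (condition
#'   `before` / `after`) of metrics, with `improvement` (pp) and `p_value`
#'   attributes. [generics::glance()] gives the one-row summary.
#' @examples
#' cohort <- simulate_cohort(cohort_template(seed = 1))
#' ill <- dplyr::filter(cohort, education_group == "illiterate")
#' glance(compare_before_after(ill))
#' @export
compare_before_after <- function(data, scheme = published_weights(),
                                 groups = education_groups(),
                                 before = c("cutoff", "svm"),
                                 cv = cv_config(), test = c("mcnemar", "bootstrap")) {
  before <- match.arg(before)
  test <- match.arg(test)
  grp <- unique(data$education_group)
  if (length(grp) != 1) {
    rlang::abort("compare_before_after expects a single education group",
      class = "mmsedw_validation_error"
    )
  }
  data <- classify_weighted(
    classify_conventional(data, groups), scheme, groups
  )
  if (before == "cutoff") {
    before_label <- data$conventional_label
    before_score <- data$total_score
  } else {
    fit <- svm_grid_search(data, cv)
    pred <- character(nrow(data))
    x <- as.matrix(data[fit$features])
    for (k in sort(unique(fit$folds))) {
      tr <- fit$folds != k
      pred[!tr] <- svm_fold_predict(
        x[tr, , drop = FALSE], data$label[tr],
        x[!tr, , drop = FALSE], fit$C, fit$gamma
      )
    }
    before_label <- ifelse(pred == "case", "impaired", "normal")
    before_score <- data$total_score
  }
  truth <- data$label
  m_before <- compute_metrics(truth, before_label)
  m_after <- compute_metrics(truth, data$weighted_label)
  correct_before <- before_label ==
    ifelse(truth == "case", "impaired", "normal")
  correct_after <- data$weighted_label ==
    ifelse(truth == "case", "impaired", "normal")
  p <- if (test == "mcnemar") {
    mcnemar_exact(correct_before, correct_after)
  } else {
    bootstrap_accuracy_test(correct_before, correct_after)
  }
  out <- dplyr::bind_rows(
    dplyr::mutate(m_before,
      group = grp, condition = "before",
      auc = rank_auc(before_score, truth), .before = 1
    ),
    dplyr::mutate(m_after,
      group = grp, condition = "after",
      auc = rank_auc(data$weighted_score, truth), .before = 1
    )
  ) |>
    dplyr::relocate(
      "group", "condition", "accuracy", "sensitivity",
      "specificity", "auc"
    )
  structure(out,
    class = c("mmsedw_eval", class(out)),
    improvement = m_after$accuracy - m_before$accuracy,
    p_value = p, test = test, before = before
  )
}

#' @export
print.mmsedw_eval <- function(x, ...) {
  cat(sprintf(
    "Before/after evaluation [%s]: improvement %+.2f pp (p = %.3g, %s)\n",
    x$group[1], attr(x, "improvement"), attr(x, "p_value"), attr(x, "test")
  ))
  NextMethod()
}

#' Tidy an evaluation
#'
#' @param x A `mmsedw_eval`.
#' @param ... Unused.
#' @return The two-row metric tibble as a plain tibble.
#' @export
tidy.mmsedw_eval <- function(x, ...) tibble::as_tibble(x)

#' One-row evaluation summary
#'
#' @param x A `mmsedw_eval`.
#' @param ... Unused.
#' @return One-row tibble: group, before/after accuracy, improvement (pp),
#'   before/after AUC, p-value.
#' @export
glance.mmsedw_eval <- function(x, ...) {
  b <- x[x$condition == "before", ]
  a <- x[x$condition == "after", ]
  tibble::tibble(
    group = b$group,
    accuracy_before = b$accuracy, accuracy_after = a$accuracy,
    improvement = attr(x, "improvement"),
    auc_before = b$auc, auc_after = a$auc,
    p_value = attr(x, "p_value")
  )
}

#' Plot a before/after evaluation
#'
#' Dot plot of accuracy, sensitivity, specificity and AUC (scaled to %)
#' before vs after weighting.
#'
#' @param object A `mmsedw_eval`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mmsedw_eval <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(auc = 100 * .data$auc) |>
    tidyr::pivot_longer(
      c("accuracy", "sensitivity", "specificity", "auc"),
      names_to = "metric", values_to = "value"
    )
  df$condition <- factor(df$condition, c("before", "after"))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$metric, y = .data$value, colour = .data$condition
  )) +
    ggplot2::geom_point(size = 3, position = ggplot2::position_dodge(0.4)) +
    ggplot2::labs(
      x = NULL, y = "%",
      title = sprintf("Diagnostic performance [%s]", df$group[1])
    )
}

#' Subgroup fairness report
#'
#' Per-education-group false-positive and false-negative rates under the
#' conventional cutoffs ("before") and the weighted scoring ("after"),
#' with the change in percentage points. A negative `fpr_change` in a
#' low-education group is the fairness outcome of interest: fewer
#' cognitively normal subjects screened as impaired.
#'
#' @param data A cohort tibble containing all groups to report.
#' @param scheme Weight scheme; defaults to the packaged published schemes.
#' @param groups Education group table.
#' @return A tibble with one row per group: `fpr_before`, `fpr_after`,
#'   `fpr_change`, `fnr_before`, `fnr_after`, `fnr_change` (percent /
#'   percentage points).
#' @export
fairness_report <- function(data, scheme = published_weights(),
                            groups = education_groups()) {
  data <- classify_weighted(
    classify_conventional(data, groups), scheme, groups
  )
  rate <- function(truth, pred) {
    m <- compute_metrics(truth, pred)
    c(fpr = 100 * m$fp / (m$fp + m$tn), fnr = 100 * m$fn / (m$fn + m$tp))
  }
  data |>
    dplyr::group_by(group = .data$education_group) |>
    dplyr::group_modify(function(d, key) {
      b <- rate(d$label, d$conventional_label)
      a <- rate(d$label, d$weighted_label)
      tibble::tibble(
        fpr_before = unname(b["fpr"]), fpr_after = unname(a["fpr"]),
        fpr_change = unname(a["fpr"] - b["fpr"]),
        fnr_before = unname(b["fnr"]), fnr_after = unname(a["fnr"]),
        fnr_change = unname(a["fnr"] - b["fnr"])
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$group, education_levels()))
}
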