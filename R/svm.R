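# Per-education-group RBF-SVM with stratified k-fold cross-validation and
# grid-search hyperparameter selection. Features are the 11 raw item
# scores, z-standardised per training fold (fit on the training part only,
# so no information leaks into the held-out fold).

#' Cross-validation configuration
#'
#' Defaults follow the study design: stratified 5-fold cross-validation
#' with a grid of penalty values C in \{0.1, 1, 5, 10, 100\} crossed with
#' kernel coefficients gamma in \{0.001, 0.01, 0.1, 1\} (20 candidate
#' pairs).
#'
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer shuffle seed for fold assignment.
#' @param c_grid Penalty parameter grid (all > 0).
#' @param gamma_grid Kernel coefficient grid (all > 0).
#' @return A list of class `mmsedw_cv`.
#' @export
cv_config <- function(n_folds = 5L, seed = 0L,
                      c_grid = c(0.1, 1, 5, 10, 100),
                      gamma_grid = c(0.001, 0.01, 0.1, 1)) {
  if (n_folds < 2) rlang::abort("n_folds must be >= 2")
  if (length(c_grid) == 0 || any(c_grid <= 0)) {
    rlang::abort("c_grid must be non-empty and > 0")
  }
  if (length(gamma_grid) == 0 || any(gamma_grid <= 0)) {
    rlang::abort("gamma_grid must be non-empty and > 0")
  }
  structure(
    list(
      n_folds = as.integer(n_folds), seed = as.integer(seed),
      c_grid = c_grid, gamma_grid = gamma_grid
    ),
    class = "mmsedw_cv"
  )
}

#' Stratified fold assignment
#'
#' Assigns each record to one of `n_folds` folds, stratified by
#' case/control label so that every fold's case fraction is within one
#' record of the overall case fraction. Deterministic for a fixed seed.
#'
#' @param data A cohort tibble (typically a single education group).
#' @param cv A [cv_config()].
#' @return Integer vector of fold indices (1..n_folds), one per row.
#' @export
stratified_folds <- function(data, cv = cv_config()) {
  n_min <- min(table(factor(data$label, c("case", "control"))))
  if (n_min < cv$n_folds) {
    rlang::abort(sprintf(
      "need at least %d records of each label for %d folds (have %d)",
      cv$n_folds, cv$n_folds, n_min
    ), class = "mmsedw_validation_error")
  }
  fold <- integer(nrow(data))
  with_preserved_seed(cv$seed, {
    for (lab in c("case", "control")) {
      idx <- which(data$label == lab)
      idx <- sample(idx)
      fold[idx] <- rep_len(seq_len(cv$n_folds), length(idx))
    }
  })
  fold
}

# Fit an RBF-SVM on standardized training features, predict the test part.
# Standardization (per-item location/scale) is fitted on training rows only.
svm_fold_predict <- function(x_train, y_train, x_test, C, gamma) {
  ctr <- colMeans(x_train)
  scl <- apply(x_train, 2, stats::sd)
  scl[scl == 0] <- 1
  xt <- scale(x_train, center = ctr, scale = scl)
  xs <- scale(x_test, center = ctr, scale = scl)
  fit <- e1071::svm(
    x = xt, y = factor(y_train, c("case", "control")),
    type = "C-classification", kernel = "radial",
    cost = C, gamma = gamma, scale = FALSE
  )
  as.character(stats::predict(fit, xs))
}

#' Cross-validated accuracy of an RBF-SVM
#'
#' For each fold: fit per-item standardisation on the training part only,
#' train an RBF-kernel soft-margin SVM with the given `C` and `gamma`,
#' score the held-out part; report the arithmetic mean of per-fold
#' accuracies in percent.
#'
#' @param data A cohort tibble (single education group expected).
#' @param C Penalty parameter.
#' @param gamma Kernel coefficient.
#' @param cv A [cv_config()].
#' @param folds Optional precomputed fold assignment (from
#'   [stratified_folds()]); recomputed from `cv` when absent.
#' @param features Item columns to use; defaults to all 11.
#' @return List with `mean_accuracy` (%) and `fold_accuracy` (% per fold).
#' @export
cross_val_accuracy <- function(data, C, gamma, cv = cv_config(),
                               folds = NULL, features = item_ids()) {
  if (is.null(folds)) folds <- stratified_folds(data, cv)
  x <- as.matrix(data[features])
  y <- data$label
  acc <- purrr::map_dbl(sort(unique(folds)), function(k) {
    tr <- folds != k
    if (length(unique(y[tr])) < 2) {
      rlang::abort("degenerate single-class training fold",
        class = "mmsedw_validation_error"
      )
    }
    pred <- svm_fold_predict(
      x[tr, , drop = FALSE], y[tr], x[!tr, , drop = FALSE], C, gamma
    )
    mean(pred == y[!tr]) * 100
  })
  list(mean_accuracy = mean(acc), fold_accuracy = acc)
}

#' Grid-search hyperparameter selection
#'
#' Evaluates every (C, gamma) pair of the grid by stratified k-fold
#' cross-validated accuracy on a shared fold assignment, selects the
#' maximiser (ties broken in favour of the first pair in C-major order),
#' and retrains the final model on the full table with the selected pair.
#'
#' @inheritParams cross_val_accuracy
#' @return An object of class `mmsedw_fit`: selected `C` and `gamma`, mean
#'   and per-fold CV accuracy at the optimum, the full `grid` of candidate
#'   accuracies, the shared fold assignment, per-item scaling parameters
#'   and the final fitted model. Use [generics::tidy()] for the grid and
#'   [generics::glance()] for the selection.
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_template(seed = 1))
#' ill <- dplyr::filter(cohort, education_group == "illiterate")
#' fit <- svm_grid_search(ill, cv_config(seed = 1))
#' glance(fit)
#' }
#' @export
svm_grid_search <- function(data, cv = cv_config(), folds = NULL,
                            features = item_ids()) {
  if (is.null(folds)) folds <- stratified_folds(data, cv)
  grid <- tidyr::expand_grid(C = cv$c_grid, gamma = cv$gamma_grid)
  res <- purrr::pmap(grid, function(C, gamma) {
    cross_val_accuracy(data, C, gamma, cv, folds = folds, features = features)
  })
  grid$mean_accuracy <- purrr::map_dbl(res, "mean_accuracy")
  best <- which.max(grid$mean_accuracy) # first maximizer, C-major order
  x <- as.matrix(data[features])
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0] <- 1
  final <- e1071::svm(
    x = scale(x, center = ctr, scale = scl),
    y = factor(data$label, c("case", "control")),
    type = "C-classification", kernel = "radial",
    cost = grid$C[best], gamma = grid$gamma[best], scale = FALSE
  )
  structure(
    list(
      C = grid$C[best], gamma = grid$gamma[best],
      mean_accuracy = grid$mean_accuracy[best],
      fold_accuracy = res[[best]]$fold_accuracy,
      grid = grid, folds = folds, cv = cv, features = features,
      scaling = tibble::tibble(item = features, center = ctr, scale = scl),
      model = final,
      group = if (length(unique(data$education_group)) == 1) {
        data$education_group[1]
      } else {
        NA_character_
      }
    ),
    class = "mmsedw_fit"
  )
}

#' @export
print.mmsedw_fit <- function(x, ...) {
  cat(sprintf(
    "RBF-SVM fit%s: C=%g, gamma=%g, mean CV accuracy %.2f%% (%d folds)\n",
    if (!is.na(x$group)) paste0(" [", x$group, "]") else "",
    x$C, x$gamma, x$mean_accuracy, length(x$fold_accuracy)
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the hyperparameter grid of a fit
#'
#' @param x A `mmsedw_fit`.
#' @param ... Unused.
#' @return Tibble of all (C, gamma) candidates with mean CV accuracy (%)
#'   and a `selected` flag.
#' @export
tidy.mmsedw_fit <- function(x, ...) {
  dplyr::mutate(x$grid, selected = .data$C == x$C & .data$gamma == x$gamma)
}

#' One-row summary of a fit
#'
#' @param x A `mmsedw_fit`.
#' @param ... Unused.
#' @return One-row tibble: group, selected C and gamma, mean CV accuracy
#'   (%), fold count.
#' @export
glance.mmsedw_fit <- function(x, ...) {
  tibble::tibble(
    group = x$group, C = x$C, gamma = x$gamma,
    mean_accuracy = x$mean_accuracy,
    n_folds = length(x$fold_accuracy),
    n = length(x$folds)
  )
}
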