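# End-to-end orchestration: stratify -> grid search per group -> ablation
# -> derive or load weights -> weighted scoring -> before/after evaluation
# -> fairness report. Every artifact lands under the run's output
# directory and is listed in the manifest; the same config and seed
# reproduce all numeric outputs.

#' Validate a run configuration
#'
#' A run config is a named list (or YAML/JSON file) with fields:
#' `input` (cohort CSV path) or `synthetic` (`list(seed = ...)`, exactly
#' one of the two), optional `cv` (`n_folds`, `seed`, `c_grid`,
#' `gamma_grid`), `weighting` (`"published"` or `"derived"`), `out_dir`
#' and `seed`. All violations are collected, not just the first.
#'
#' @param config A named list or a path to a YAML/JSON file.
#' @return The parsed config list, invisibly, if valid; otherwise an error
#'   listing every violation.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      rlang::abort(paste0("config file not found: ", config),
        class = "mmsedw_io_error"
      )
    }
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  errors <- character()
  has_input <- !is.null(config$input)
  has_synth <- !is.null(config$synthetic)
  if (has_input == has_synth) {
    errors <- c(errors, "exactly one of 'input' and 'synthetic' must be set")
  }
  if (has_input && !has_synth && !file.exists(config$input)) {
    errors <- c(errors, paste0("input file not found: ", config$input))
  }
  if (!is.null(config$weighting) &&
    !config$weighting %in% c("published", "derived")) {
    errors <- c(errors, "weighting must be 'published' or 'derived'")
  }
  if (!is.null(config$cv)) {
    cv <- config$cv
    if (!is.null(cv$n_folds) && cv$n_folds < 2) {
      errors <- c(errors, "cv$n_folds must be >= 2")
    }
    if (!is.null(cv$c_grid) && any(cv$c_grid <= 0)) {
      errors <- c(errors, "cv$c_grid values must be > 0")
    }
    if (!is.null(cv$gamma_grid) && any(cv$gamma_grid <= 0)) {
      errors <- c(errors, "cv$gamma_grid values must be > 0")
    }
  }
  if (length(errors) > 0) {
    rlang::abort(
      paste0(
        "invalid run config:\n",
        paste0("  - ", errors, collapse = "\n")
      ),
      class = "mmsedw_validation_error"
    )
  }
  invisible(config)
}

resolve_cv <- function(config) {
  cv <- config$cv
  cv_config(
    n_folds = cv$n_folds %||% 5L,
    seed = cv$seed %||% config$seed %||% 0L,
    c_grid = cv$c_grid %||% c(0.1, 1, 5, 10, 100),
    gamma_grid = cv$gamma_grid %||% c(0.001, 0.01, 0.1, 1)
  )
}

#' Run the full pipeline
#'
#' Executes stratification, per-group grid search, item-deletion analysis,
#' weight derivation (or the packaged published schemes), weighted scoring
#' and before/after evaluation with a fairness report, writing every
#' artifact under `out_dir` and returning a manifest.
#'
#' @param config A run config list or YAML/JSON path (see
#'   [validate_run_config()]).
#' @param quiet Suppress per-stage log lines.
#' @return A list with `manifest` (tibble of artifact paths), `fits`,
#'   `ablations`, `scheme`, `evaluations` and `fairness`.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(
#'   synthetic = list(seed = 1), weighting = "published",
#'   out_dir = tempfile("run"), seed = 1
#' ))
#' out$manifest
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- validate_run_config(config)
  out_dir <- config$out_dir %||% tempfile("mmsedw_run")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 0L)
  cv <- resolve_cv(config)
  log_line <- function(stage, ...) {
    if (!quiet) {
      message(sprintf("[%s] seed=%d %s", stage, seed, sprintf(...)))
    }
  }
  artifacts <- list()
  emit <- function(name, path) {
    artifacts[[name]] <<- path
    path
  }
  stage <- "load"
  withCallingHandlers(
    {
      if (!is.null(config$input)) {
        cohort <- read_cohort(config$input)
        log_line(stage, "read %d records from %s", nrow(cohort), config$input)
      } else {
        tpl <- cohort_template(seed = config$synthetic$seed %||% seed)
        cohort <- simulate_cohort(tpl)
        write_cohort(cohort, emit("cohort", file.path(out_dir, "cohort.csv")))
        log_line(stage, "simulated %d records", nrow(cohort))
      }

      groups_present <- intersect(
        education_levels(), unique(cohort$education_group)
      )
      stage <- "fit"
      fits <- purrr::map(groups_present, function(g) {
        d <- cohort[cohort$education_group == g, ]
        fit <- svm_grid_search(d, cv)
        log_line(
          stage, "group=%s C=%g gamma=%g acc=%.2f%%",
          g, fit$C, fit$gamma, fit$mean_accuracy
        )
        fit
      })
      names(fits) <- groups_present
      jsonlite::write_json(
        purrr::map(fits, function(f) {
          list(
            group = f$group, C = f$C, gamma = f$gamma,
            mean_accuracy = f$mean_accuracy,
            fold_accuracy = f$fold_accuracy
          )
        }),
        emit("fits", file.path(out_dir, "fits.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )

      stage <- "ablate"
      ablations <- purrr::imap(fits, function(f, g) {
        abl <- ablate_items(
          cohort[cohort$education_group == g, ],
          cv,
          fit = f
        )
        log_line(
          stage, "group=%s critical=%d interference=%d",
          g, sum(abl$category == "critical"),
          sum(abl$category == "interference")
        )
        abl
      })
      jsonlite::write_json(
        purrr::map(ablations, function(a) {
          list(
            group = a$group[1],
            baseline_accuracy = baseline_accuracy(a),
            items = tibble::as_tibble(a)[
              c("item", "post_accuracy", "delta", "category")
            ]
          )
        }),
        emit("ablations", file.path(out_dir, "ablations.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )
      contribution_matrix(
        unname(ablations),
        path = emit(
          "contribution_matrix",
          file.path(out_dir, "contribution_matrix.csv")
        )
      )

      stage <- "weights"
      weighting <- config$weighting %||% "published"
      scheme <- if (weighting == "published") {
        published_weights()
      } else {
        purrr::map(ablations, derive_weights) |> purrr::list_rbind()
      }
      scheme <- scheme[scheme$group %in% groups_present, ]
      write_weight_schemes(
        scheme,
        emit("weights", file.path(out_dir, "weights.json"))
      )
      log_line(stage, "mode=%s", weighting)

      stage <- "score"
      scored <- classify_weighted(
        classify_conventional(cohort), scheme
      )
      readr::write_csv(
        scored[c(
          "subject_id", "education_group", "label", "total_score",
          "conventional_label", "weighted_score", "weighted_label"
        )],
        emit("scores", file.path(out_dir, "scores.csv")),
        progress = FALSE
      )

      stage <- "evaluate"
      evaluations <- purrr::map(groups_present, function(g) {
        ev <- compare_before_after(
          cohort[cohort$education_group == g, ], scheme
        )
        log_line(
          stage, "group=%s improvement=%+.2fpp p=%.3g",
          g, attr(ev, "improvement"), attr(ev, "p_value")
        )
        ev
      })
      names(evaluations) <- groups_present
      jsonlite::write_json(
        purrr::map(evaluations, function(ev) {
          list(
            metrics = tibble::as_tibble(ev),
            improvement = attr(ev, "improvement"),
            p_value = attr(ev, "p_value")
          )
        }),
        emit("evaluations", file.path(out_dir, "evaluations.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )

      stage <- "fairness"
      fair <- fairness_report(cohort, scheme)
      readr::write_csv(
        fair, emit("fairness", file.path(out_dir, "fairness.csv")),
        progress = FALSE
      )
    },
    error = function(e) {
      marker <- file.path(out_dir, paste0(stage, ".failed"))
      writeLines(conditionMessage(e), marker)
      rlang::abort(
        sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
        parent = e
      )
    }
  )

  manifest <- tibble::tibble(
    artifact = names(artifacts),
    path = unlist(artifacts)
  )
  config_echo <- list(
    input = config$input, synthetic = config$synthetic,
    weighting = config$weighting %||% "published",
    seed = seed,
    cv = list(
      n_folds = cv$n_folds, seed = cv$seed,
      c_grid = cv$c_grid, gamma_grid = cv$gamma_grid
    ),
    out_dir = out_dir,
    package_version = as.character(utils::packageVersion("mmsedw")),
    artifacts = as.list(artifacts)
  )
  jsonlite::write_json(
    config_echo, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  manifest <- dplyr::bind_rows(
    manifest,
    tibble::tibble(
      artifact = "manifest", path = file.path(out_dir, "manifest.json")
    )
  )
  list(
    manifest = manifest, fits = fits, ablations = ablations,
    scheme = scheme, evaluations = evaluations, fairness = fair
  )
}
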