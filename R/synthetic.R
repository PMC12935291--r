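# Latent-severity synthetic cohorts.
#
# Each subject carries a latent severity s ~ Normal(mu_label, sigma); each
# subitem responds through a two-parameter logistic link,
#   p_{g,i} = plogis(alpha_{g,i} - beta_{g,i} * s),  clipped to [0.02, 0.98],
#   v_i ~ Binomial(max_score_i, p_{g,i}).
# A shared latent trait (rather than independent item noise) makes total
# scores, item correlations and AUC behave like real psychometric data.
# alpha is the baseline easiness of the item for the group (log-odds at
# s = 0); beta is its discriminability for the group. beta = 0 yields a
# pure noise item; negative beta yields an anti-signal item.

#' Construct a synthetic-cohort configuration
#'
#' @param counts Tibble with columns `group`, `cases`, `controls` giving
#'   per-stratum sample sizes.
#' @param effects Tibble with columns `group`, `item`, `alpha`
#'   (baseline easiness, log-odds units) and `beta` (discriminability,
#'   dimensionless) covering every (group, item) pair in `counts`.
#' @param mu_case,mu_control Latent severity means for cases and controls.
#'   A well-posed signal needs `mu_case > mu_control` (warned otherwise).
#' @param sigma Latent severity spread (> 0).
#' @param seed Integer seed stored with the config; [simulate_cohort()]
#'   uses it unless overridden.
#' @return A validated config object (class `mmsedw_config`).
#' @seealso [cohort_template()] for the packaged default configuration.
#' @export
cohort_config <- function(counts, effects, mu_case = 1, mu_control = -1,
                          sigma = 1, seed = 0L) {
  cfg <- structure(
    list(
      counts = tibble::as_tibble(counts),
      effects = tibble::as_tibble(effects),
      mu_case = mu_case, mu_control = mu_control,
      sigma = sigma, seed = as.integer(seed)
    ),
    class = "mmsedw_config"
  )
  validate_config(cfg)
  cfg
}

#' Validate a synthetic-cohort configuration
#'
#' @param config A `mmsedw_config` object.
#' @return `config`, invisibly; errors on structural violations, warns on
#'   an ill-posed signal (`mu_case <= mu_control`) or anti-signal items
#'   (`beta < 0`).
#' @export
validate_config <- function(config) {
  if (!inherits(config, "mmsedw_config")) {
    rlang::abort("not a mmsedw_config object", class = "mmsedw_validation_error")
  }
  cts <- config$counts
  if (!all(c("group", "cases", "controls") %in% names(cts))) {
    rlang::abort("counts needs columns group, cases, controls",
      class = "mmsedw_validation_error"
    )
  }
  if (any(cts$cases < 0 | cts$controls < 0)) {
    rlang::abort("counts must be >= 0", class = "mmsedw_validation_error")
  }
  if (!all(cts$group %in% education_levels())) {
    rlang::abort("unknown group in counts", class = "mmsedw_validation_error")
  }
  if (!is.numeric(config$sigma) || config$sigma <= 0) {
    rlang::abort("sigma must be > 0", class = "mmsedw_validation_error")
  }
  eff <- config$effects
  need <- tidyr::expand_grid(group = cts$group, item = item_ids())
  have <- paste(eff$group, eff$item)
  gap <- need[!paste(need$group, need$item) %in% have, ]
  if (nrow(gap) > 0) {
    rlang::abort(sprintf(
      "effects missing alpha/beta for (%s, %s)", gap$group[1], gap$item[1]
    ), class = "mmsedw_validation_error")
  }
  if (anyNA(eff$alpha) || anyNA(eff$beta)) {
    rlang::abort("alpha/beta must be finite", class = "mmsedw_validation_error")
  }
  if (config$mu_case <= config$mu_control) {
    rlang::warn("mu_case <= mu_control: cases will not score lower than controls")
  }
  if (any(eff$beta < 0)) {
    rlang::warn("negative beta present: item(s) act as anti-signal")
  }
  invisible(config)
}

#' Packaged default synthetic configuration
#'
#' Emulates the qualitative structure of an education-stratified screening
#' cohort: stratum sizes 108/105/364/235 with case/control splits 60/48,
#' 53/52, 185/179 and 106/129; spatial orientation and immediate memory
#' dominate the signal in the illiterate stratum; temporal orientation and
#' calculation carry the signal in the secondary stratum; the secondary and
#' university strata contain pure-noise (interference) items; and literacy
#' items (reading, writing, pentagon copy, serial sevens) are hard for
#' low-education subjects regardless of impairment, which inflates
#' false-positive screens under the conventional cutoffs exactly where an
#' education-adjusted method should help. All alpha/beta values are package
#' defaults chosen for realism, not estimates from any dataset.
#'
#' @param seed Integer seed stored in the config.
#' @return A `mmsedw_config` object.
#' @examples
#' cohort <- simulate_cohort(cohort_template(seed = 42))
#' dplyr::count(cohort, education_group, label)
#' @export
cohort_template <- function(seed = 0L) {
  counts <- tibble::tibble(
    group = education_levels(),
    cases = c(60L, 53L, 185L, 106L),
    controls = c(48L, 52L, 179L, 129L)
  )
  base <- function(group, alpha_default, beta_default) {
    tibble::tibble(
      group = group, item = item_ids(),
      alpha = alpha_default, beta = beta_default
    )
  }
  set_eff <- function(eff, items, alpha = NULL, beta = NULL) {
    i <- match(items, eff$item)
    if (!is.null(alpha)) eff$alpha[i] <- alpha
    if (!is.null(beta)) eff$beta[i] <- beta
    eff
  }
  illiterate <- base("illiterate", 1.2, 0.7) |>
    set_eff(c("space_orientation", "immediate_memory"), beta = c(2.5, 2.0)) |>
    set_eff(c("reading", "writing", "spatial_structure"),
      alpha = -0.5, beta = 0.2
    ) |>
    set_eff("attention_calculation", alpha = 0.0, beta = 0.3)
  primary <- base("primary", 1.7, 1.2) |>
    set_eff(c("reading", "writing", "spatial_structure"), alpha = 1.0) |>
    set_eff("spatial_structure", beta = 0) |>
    set_eff("execution_ability", beta = 1.5)
  secondary <- base("secondary", 1.8, 0.4) |>
    set_eff(c("time_orientation", "attention_calculation"), beta = 1.8) |>
    set_eff(
      c(
        "space_orientation", "immediate_memory", "delayed_memory",
        "execution_ability", "reading", "spatial_structure"
      ),
      beta = 0
    )
  university <- base("university", 1.8, 0.5) |>
    set_eff("attention_calculation", beta = 2.0) |>
    set_eff(c("execution_ability", "repetition", "reading"),
      beta = c(1.5, 0.8, 0.8)
    ) |>
    set_eff(
      c(
        "space_orientation", "immediate_memory", "naming",
        "delayed_memory"
      ),
      alpha = 3.0, beta = 0
    )
  cohort_config(
    counts = counts,
    effects = dplyr::bind_rows(illiterate, primary, secondary, university),
    mu_case = 1, mu_control = -1, sigma = 1, seed = seed
  )
}

#' Simulate an education-stratified case/control cohort
#'
#' Draws a cohort from the latent-severity binomial item-response model
#' described in [cohort_config()]. The same config and seed always yield
#' the identical table.
#'
#' @param config A `mmsedw_config` object.
#' @param seed Integer seed; defaults to `config$seed`.
#' @param bank Item bank, by default [mmse_item_bank()].
#' @return A cohort tibble with `provenance = "synthetic"`.
#' @export
simulate_cohort <- function(config, seed = config$seed,
                            bank = mmse_item_bank()) {
  validate_config(config)
  with_preserved_seed(seed, {
    rows <- purrr::pmap(config$counts, function(group, cases, controls) {
      n <- cases + controls
      if (n == 0) {
        return(NULL)
      }
      label <- c(rep("case", cases), rep("control", controls))
      mu <- ifelse(label == "case", config$mu_case, config$mu_control)
      s <- stats::rnorm(n, mu, config$sigma)
      eff <- config$effects[config$effects$group == group, ]
      eff <- eff[match(bank$item, eff$item), ]
      scores <- purrr::map(seq_len(nrow(bank)), function(i) {
        p <- stats::plogis(eff$alpha[i] - eff$beta[i] * s)
        p <- pmin(pmax(p, 0.02), 0.98)
        stats::rbinom(n, bank$max_score[i], p)
      })
      names(scores) <- bank$item
      tibble::tibble(
        education_group = group, label = label, !!!scores
      )
    }) |> purrr::list_rbind()
    if (is.null(rows) || nrow(rows) == 0) {
      rows <- tibble::tibble(
        education_group = character(), label = character(),
        !!!stats::setNames(
          rep(list(integer()), nrow(bank)), bank$item
        )
      )
    }
    out <- dplyr::bind_cols(
      tibble::tibble(
        subject_id = sprintf("S%04d", seq_len(nrow(rows))),
        provenance = "synthetic"
      ),
      rows
    )
    out <- out[c(
      "subject_id", "education_group", "label", "provenance", bank$item
    )]
    if (nrow(out) > 0) validate_cohort(out, bank)
    out
  })
}

# Run code under a given seed, restoring the caller's RNG state after.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
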