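test_that("the contribution statistic is post minus baseline accuracy", {
  expect_equal(delta_accuracy(85.71, 83.81), -1.90)
  expect_equal(delta_accuracy(42.5, 42.5), 0)
  expect_equal(delta_accuracy(69.78, 73.35), 3.57)
  expect_error(delta_accuracy(-5, 50))
})

test_that("items are categorised by the strict delta thresholds", {
  expect_equal(delta_category(-6.58), "critical")
  expect_equal(delta_category(0.95), "interference")
  expect_equal(delta_category(0), "neutral")
  # boundary values are neutral (strict inequalities)
  expect_equal(delta_category(c(-1.0, 0.5)), c("neutral", "neutral"))
  expect_equal(delta_category(c(-1.001, 0.501)), c("critical", "interference"))
  expect_error(delta_category(NaN))
})

test_that("ablation covers all 11 items, deterministically, with frozen folds", {
  cohort <- simulate_cohort(planted_config(
    c(0, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    cases = 60, controls = 60, seed = 7
  ))
  cv <- cv_config(seed = 7, c_grid = c(1, 10), gamma_grid = c(0.01, 0.1))
  fit <- svm_grid_search(cohort, cv)
  abl <- ablate_items(cohort, cv, fit = fit)
  expect_s3_class(abl, "mmsedw_ablation")
  expect_equal(nrow(abl), 11)
  expect_setequal(abl$item, mmse_item_bank()$item)
  expect_equal(abl$delta, abl$post_accuracy - baseline_accuracy(abl))
  expect_equal(abl$category, delta_category(abl$delta))

  # brute-force re-run with the same seed reproduces every delta exactly
  again <- ablate_items(cohort, cv, fit = fit)
  expect_equal(as.data.frame(again), as.data.frame(abl))
  redo <- vapply(abl$item, function(it) {
    cross_val_accuracy(cohort, fit$C, fit$gamma, cv,
      folds = fit$folds,
      features = setdiff(mmse_item_bank()$item, it)
    )$mean_accuracy
  }, numeric(1))
  expect_equal(unname(redo), abl$post_accuracy)

  expect_error(
    ablate_items(simulate_cohort(cohort_template(seed = 1)), cv),
    "single education group"
  )
})

test_that("a planted dominant item attains the most negative delta", {
  hits <- vapply(1:6, function(s) {
    cohort <- simulate_cohort(planted_config(
      c(0, 2, 0, 0, 0, 0, 0, 0, 0, 0, 0), # space_orientation only
      cases = 75, controls = 75, seed = s
    ))
    cv <- cv_config(seed = s, c_grid = 1, gamma_grid = 0.1)
    abl <- ablate_items(cohort, cv)
    abl$item[which.min(abl$delta)] == "space_orientation"
  }, logical(1))
  expect_gte(sum(hits), 5)
})

test_that("pure-noise cohorts produce no consistently critical item", {
  crit <- lapply(1:4, function(s) {
    cohort <- simulate_cohort(planted_config(rep(0, 11),
      cases = 50, controls = 50, seed = s
    ))
    cv <- cv_config(seed = s, c_grid = 1, gamma_grid = 0.1)
    abl <- ablate_items(cohort, cv)
    abl$item[abl$category == "critical"]
  })
  always_critical <- Reduce(intersect, crit)
  expect_equal(length(always_critical), 0)
})

test_that("removing a duplicated column costs nothing", {
  # a copied column adds no information on top of its twin when the
  # remaining items carry the signal: deleting the copy is near-neutral
  deltas <- vapply(1:10, function(s) {
    cohort <- simulate_cohort(planted_config(rep(1, 11),
      cases = 75, controls = 75, seed = s
    ))
    cohort$attention_calculation <- cohort$space_orientation # exact copy
    cv <- cv_config(seed = s, c_grid = 1, gamma_grid = 0.1)
    abl <- ablate_items(cohort, cv)
    abl$delta[abl$item == "attention_calculation"]
  }, numeric(1))
  expect_lt(abs(mean(deltas)), 1)
})

test_that("the contribution matrix binds groups in canonical order", {
  mk <- function(group, seed) {
    cohort <- simulate_cohort(planted_config(
      c(0, 2, 1, 0, 0, 0, 0, 0, 0, 0, 0),
      group = group, cases = 40, controls = 40, seed = seed
    ))
    ablate_items(cohort, cv_config(seed = seed, c_grid = 1, gamma_grid = 0.1))
  }
  res <- list(mk("illiterate", 1), mk("secondary", 2))
  expect_warning(m <- contribution_matrix(res), "primary")
  expect_equal(dim(m), c(2, 12))
  expect_equal(m$group, c("illiterate", "secondary"))
  expect_equal(names(m)[-1], mmse_item_bank()$item)
  expect_equal(
    m$space_orientation[1],
    res[[1]]$delta[res[[1]]$item == "space_orientation"]
  )
  path <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings(contribution_matrix(res, path = path))
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(m))

  p <- autoplot(res[[1]])
  expect_s3_class(p, "ggplot")
})
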