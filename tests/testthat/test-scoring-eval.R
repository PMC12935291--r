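test_that("weighted scores hit the documented anchors", {
  bank <- mmse_item_bank()
  for (g in education_levels()) {
    maxed <- add_weighted_score(toy_record(bank$max_score, group = g))
    expect_equal(maxed$weighted_score, 60)
    zeroed <- add_weighted_score(toy_record(rep(0, 11), group = g))
    expect_equal(zeroed$weighted_score, 0)
  }
  # illiterate, one writing point lost: 60 - w_writing * 1 * factor(=1) = 58
  scores <- bank$max_score
  scores[bank$item == "writing"] <- 0
  got <- add_weighted_score(toy_record(scores, group = "illiterate"))
  expect_equal(got$weighted_score, 58)
})

test_that("weighted classification uses S < T with a >= boundary", {
  rec <- toy_record(mmse_item_bank()$max_score)
  low <- dplyr::mutate(rec) |> add_weighted_score()
  low$weighted_score <- 29.9
  expect_equal(classify_weighted(low)$weighted_label, "impaired")
  low$weighted_score <- 30.0
  expect_equal(classify_weighted(low)$weighted_label, "normal")
  maxed <- classify_weighted(rec)
  expect_equal(maxed$weighted_label, "normal")
})

test_that("confusion metrics match hand counts and flag degeneracy", {
  perfect <- compute_metrics(
    c("case", "control"), c("impaired", "normal")
  )
  expect_equal(
    c(perfect$accuracy, perfect$sensitivity, perfect$specificity),
    c(100, 100, 100)
  )
  m <- compute_metrics(
    c(rep("case", 4), rep("control", 4)),
    c(
      "impaired", "impaired", "impaired", "normal",
      "normal", "normal", "impaired", "impaired"
    )
  )
  expect_equal(m$accuracy, 62.5)
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 50)
  all_imp <- compute_metrics(
    c("case", "control"), c("impaired", "impaired")
  )
  expect_equal(all_imp$sensitivity, 100)
  expect_equal(all_imp$specificity, 0)
  onlycases <- compute_metrics(c("case", "case"), c("impaired", "normal"))
  expect_true(is.na(onlycases$specificity))
  expect_false(is.na(onlycases$sensitivity))
})

test_that("rank AUC matches brute force, pROC and monotone invariance", {
  mmsedw:::with_preserved_seed(42, {
    for (rep in 1:10) {
      n <- 30
      truth <- sample(c("case", "control"), n, replace = TRUE,
        prob = c(0.5, 0.5)
      )
      if (length(unique(truth)) < 2) next
      scores <- sample(0:10, n, replace = TRUE) # many ties
      a <- rank_auc(scores, truth)
      expect_equal(a, auc_bruteforce(scores, truth))
      # invariant under strictly monotone transforms
      expect_equal(rank_auc(scores^3 + 2, truth), a)
    }
  })
  # perfectly separated scores
  expect_equal(
    rank_auc(c(1, 2, 3, 10, 11, 12), c(rep("case", 3), rep("control", 3))),
    1
  )
  # independent labels hover around 0.5
  null_auc <- vapply(1:20, function(s) {
    mmsedw:::with_preserved_seed(s, {
      rank_auc(stats::rnorm(60), sample(rep(c("case", "control"), 30)))
    })
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)
  skip_if_not_installed("pROC")
  mmsedw:::with_preserved_seed(7, {
    truth <- rep(c("case", "control"), each = 25)
    scores <- stats::rnorm(50) + (truth == "control")
    expect_equal(
      rank_auc(scores, truth),
      as.numeric(pROC::auc(pROC::roc(
        response = truth, predictor = scores,
        levels = c("case", "control"), direction = "<", quiet = TRUE
      )))
    )
  })
})

test_that("exact McNemar behaves on degenerate and simple tables", {
  expect_equal(mcnemar_exact(rep(TRUE, 10), rep(TRUE, 10)), 1)
  # 6 vs 0 discordant pairs: exact binomial two-sided
  b6 <- c(rep(TRUE, 6), rep(FALSE, 4))
  a6 <- c(rep(FALSE, 6), rep(FALSE, 4))
  expect_equal(
    mcnemar_exact(b6, a6),
    stats::binom.test(6, 6, 0.5)$p.value
  )
  p_boot <- bootstrap_accuracy_test(b6, a6, n_boot = 500, seed = 1)
  expect_lt(p_boot, 0.2)
})

test_that("before/after comparison reconciles with independent recomputation", {
  cohort <- simulate_cohort(cohort_template(seed = 5))
  ill <- dplyr::filter(cohort, education_group == "illiterate")
  ev <- compare_before_after(ill)
  expect_s3_class(ev, "mmsedw_eval")
  expect_equal(nrow(ev), 2)

  labelled <- classify_weighted(classify_conventional(ill))
  m_before <- compute_metrics(labelled$label, labelled$conventional_label)
  m_after <- compute_metrics(labelled$label, labelled$weighted_label)
  expect_equal(
    attr(ev, "improvement"),
    m_after$accuracy - m_before$accuracy
  )
  expect_equal(ev$accuracy, c(m_before$accuracy, m_after$accuracy))
  expect_equal(
    ev$auc,
    c(
      rank_auc(labelled$total_score, labelled$label),
      rank_auc(labelled$weighted_score, labelled$label)
    )
  )
  g <- glance(ev)
  expect_equal(g$improvement, attr(ev, "improvement"))
  expect_true(g$p_value >= 0 && g$p_value <= 1)
  expect_s3_class(autoplot(ev), "ggplot")

  # identical before/after correctness: no discordant pairs, p = 1
  expect_equal(mcnemar_exact(c(TRUE, FALSE), c(TRUE, FALSE)), 1)
})

test_that("fairness rates reconcile with specificity and sensitivity", {
  cohort <- simulate_cohort(cohort_template(seed = 6))
  fair <- fairness_report(cohort)
  expect_equal(fair$group, education_levels())
  labelled <- classify_weighted(classify_conventional(cohort))
  for (g in education_levels()) {
    d <- dplyr::filter(labelled, education_group == g)
    m <- compute_metrics(d$label, d$conventional_label)
    expect_equal(
      fair$fpr_before[fair$group == g], 100 - m$specificity
    )
    expect_equal(
      fair$fnr_before[fair$group == g], 100 - m$sensitivity
    )
  }
  # the designed fairness outcome: conventional false positives in the
  # illiterate stratum shrink under weighted scoring
  changes <- vapply(1:5, function(s) {
    f <- fairness_report(simulate_cohort(cohort_template(seed = s)))
    f$fpr_change[f$group == "illiterate"]
  }, numeric(1))
  expect_lt(mean(changes), 0)
})
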