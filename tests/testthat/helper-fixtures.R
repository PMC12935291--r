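# Shared fixtures, built in code.

# A single-row cohort tibble from 11 raw item scores (canonical order).
toy_record <- function(scores, group = "illiterate", label = "case",
                       id = "S0001") {
  bank <- mmse_item_bank()
  stopifnot(length(scores) == 11)
  tibble::tibble(
    subject_id = id, education_group = group, label = label,
    !!!stats::setNames(as.list(as.integer(scores)), bank$item)
  )
}

# A cohort of n random valid records spread over all four groups.
toy_random_cohort <- function(n, seed = 1) {
  bank <- mmse_item_bank()
  mmsedw:::with_preserved_seed(seed, {
    scores <- lapply(seq_len(nrow(bank)), function(i) {
      sample(0:bank$max_score[i], n, replace = TRUE)
    })
    names(scores) <- bank$item
    tibble::tibble(
      subject_id = sprintf("R%05d", seq_len(n)),
      education_group = sample(education_levels(), n, replace = TRUE),
      label = sample(c("case", "control"), n, replace = TRUE),
      !!!scores
    )
  })
}

# Two well-separated clusters: cases low on every item, controls high.
# The classes are linearly (hence RBF-) separable by a wide margin.
toy_separable <- function(n_per_class = 20, group = "primary", seed = 1) {
  bank <- mmse_item_bank()
  mmsedw:::with_preserved_seed(seed, {
    mk <- function(label, lo) {
      scores <- lapply(bank$max_score, function(m) {
        if (lo) {
          sample(0:min(1, m), n_per_class, replace = TRUE)
        } else {
          sample(max(0, m - 1):m, n_per_class, replace = TRUE)
        }
      })
      names(scores) <- bank$item
      tibble::tibble(
        education_group = group,
        label = label, !!!scores
      )
    }
    out <- dplyr::bind_rows(mk("case", TRUE), mk("control", FALSE))
    out$subject_id <- sprintf("T%04d", seq_len(nrow(out)))
    dplyr::relocate(out, "subject_id")
  })
}

# Single-group synthetic config with per-item discriminabilities `beta`
# (length 11, canonical order) and common baseline easiness `alpha`.
planted_config <- function(beta, alpha = 1.5, group = "secondary",
                           cases = 150, controls = 150, seed = 0L) {
  stopifnot(length(beta) == 11)
  cohort_config(
    counts = tibble::tibble(
      group = group, cases = cases, controls = controls
    ),
    effects = tibble::tibble(
      group = group, item = mmse_item_bank()$item,
      alpha = alpha, beta = beta
    ),
    seed = seed
  )
}

# Brute-force all-pairs AUC oracle (impairment-positive orientation).
auc_bruteforce <- function(scores, truth) {
  cs <- scores[truth == "case"]
  ct <- scores[truth == "control"]
  tot <- 0
  for (a in cs) {
    for (b in ct) {
      tot <- tot + (b > a) + 0.5 * (b == a)
    }
  }
  tot / (length(cs) * length(ct))
}
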