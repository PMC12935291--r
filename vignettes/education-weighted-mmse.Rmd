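---
title: "Education-stratified dynamic weighting of MMSE subitems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Education-stratified dynamic weighting of MMSE subitems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmsedw)
library(dplyr)
```

## The problem

The Mini-Mental State Examination (MMSE) is an 11-subitem, 30-point
screening instrument for cognitive impairment. Its diagnostic behaviour
depends strongly on schooling: literacy-loaded subitems (reading, writing,
calculation, figure copying) penalise cognitively normal adults with little
formal education, inflating false-positive screens, while highly educated
adults can compensate on easy items and evade detection. Education-adjusted
*total-score* cutoffs (illiterate &le; 17, primary &le; 20, secondary
&le; 22, university &le; 23, from Chinese normative practice) shift the
threshold but leave every subitem weighted equally, so they cannot express
that a given subitem is informative in one stratum and noise in another.

`mmsedw` implements an education-stratified, item-level alternative:

1. **Stratify** subjects into illiterate / primary / secondary / university
   cohorts and model each separately.
2. **Classify** within each stratum with an RBF-kernel soft-margin SVM on
   the 11 raw item scores, using stratified 5-fold cross-validation (fold
   assignment preserves the case/control ratio) and a grid search over
   `C` &isin; {0.1, 1, 5, 10, 100} &times; `gamma` &isin;
   {0.001, 0.01, 0.1, 1} (20 candidates; mean CV accuracy selects the
   pair, first maximiser in C-major order on ties).
3. **Ablate**: delete each subitem in turn, retrain on the remaining 10
   with the *same* folds and the *same* (C, gamma), and record
   &Delta;<sub>i</sub> = post-deletion accuracy &minus; baseline accuracy
   (percentage points). Negative &Delta; means the item helped. Items with
   &Delta; &lt; &minus;1.0 are *critical*, &Delta; &gt; +0.5 are
   *interference*, all others *neutral*; boundary values are neutral
   because the thresholds are strict.
4. **Weight**: map categories to integer weights (critical &rarr; 3,
   neutral &rarr; 2, interference &rarr; 1) or load the packaged published
   schemes, and score each subject as
   S = &Sigma;<sub>i</sub> v<sub>i</sub> w<sub>i</sub>, linearly rescaled
   by 60 / max_raw so the maximal response scores exactly 60 in every
   group. A subject screens impaired when S &lt; T with group thresholds
   T = 30 / 31 / 32 / 33.
5. **Evaluate**: accuracy, sensitivity, specificity, rank-based AUC
   (impairment-positive, midranks for ties) before (conventional cutoffs)
   versus after (weighted scoring), the accuracy improvement in
   percentage points, an exact McNemar test on paired per-subject
   correctness, and per-group false-positive / false-negative rates as
   the fairness outcome.

## Model and assumptions

The classifier sees only the 11 raw item scores; age and sex, when
present, are carried as metadata but deliberately excluded from the
feature vector so that the ablation statistic is an item-level quantity.
Features are z-standardised per training fold (location and scale fitted
on the training part only — an RBF kernel needs comparable scales, and
fitting on the full fold pair would leak held-out information). Class
weighting is off by default because the strata are near-balanced.

The item bank uses the standard Folstein point allocation
(5, 5, 3, 5, 3, 2, 1, 3, 1, 1, 1; total 30). Two mappings are worth
stating because MMSE dialects differ: *execution ability* is the 3-point
three-stage command and *spatial structure* the 1-point pentagon copy.
This allocation is an assumption of the package; it is the unique standard
allocation under which the packaged weight tables attain raw weighted
maxima of 60, 60, 59 and 57 for the four groups, which is also why the
60-point normalisation (`raw * 60 / max_raw`) is interpreted as a
per-group *linear* rescaling: it is the only linear map that sends every
group's maximal response to a common ceiling of 60. Normalised scores are
kept real-valued (not rounded); rounding would discard resolution that the
rank-based AUC uses.

### Weight derivation versus packaged schemes

`derive_weights()` implements the documented category rule
(critical/neutral/interference &rarr; 3/2/1), a monotone step function of
&Delta;. The packaged schemes in `published_weights()` are shipped as
authoritative constants for scoring, and `derive_weights()` is *not*
claimed to regenerate them: no simple thresholding of a contribution
profile reproduces those tables (for example, a strongly critical
immediate-memory item can still carry weight 2 there). Both halves are
therefore exposed separately — the rule for reproducible derivation from
your own data, the constants for scoring with the fixed published
calibration — and `run_pipeline()`'s `weighting` switch selects between
them.

### Before/after contrast

The "before" condition defaults to the conventional education-adjusted
cutoffs applied to the total score, which matches the framing of a
scoring-rule comparison; `compare_before_after(before = "svm")` instead
evaluates the cross-validated baseline SVM predictions, for users who want
the machine-learning baseline as the reference. The paired significance
test is an exact McNemar test (exact binomial on discordant pairs) — the
standard test for two classifiers evaluated on the same subjects; a
subject-level percentile bootstrap is available behind
`test = "bootstrap"`.

## The synthetic cohort generator

No subject-level clinical data ship with the package, so
`simulate_cohort()` generates education-stratified case/control cohorts
from a latent-trait item-response model: each subject draws a latent
severity s ~ Normal(&mu;<sub>label</sub>, &sigma;), and item *i* in group
*g* yields v<sub>i</sub> ~ Binomial(max<sub>i</sub>, p) with
p = logistic(&alpha;<sub>g,i</sub> &minus; &beta;<sub>g,i</sub> s)
clipped to [0.02, 0.98]. The shared latent trait induces realistic
inter-item correlations and unimodal total-score distributions, which is
what makes AUC and threshold behaviour meaningful; the clipping keeps
every item stochastic so no fold degenerates.

`cohort_template()` is the packaged default configuration and defines the
generator's study conditions: stratum sizes 108 / 105 / 364 / 235 with
case/control splits 60/48, 53/52, 185/179 and 106/129, severity means
&mu;<sub>case</sub> = 1, &mu;<sub>control</sub> = &minus;1 and
&sigma; = 1. Its effect patterns encode the qualitative structure the
method targets:

- **illiterate** — spatial orientation (&beta; = 2.5) and immediate memory
  (&beta; = 2.0) dominate the signal; literacy items (reading, writing,
  pentagon copy: &alpha; = &minus;0.5, &beta; = 0.2; serial sevens:
  &alpha; = 0) are hard for everyone, so cognitively normal subjects lose
  points there and cross the conventional cutoff — the education-dependent
  false-positive mechanism.
- **primary** — broadly informative items (&beta; = 1.2-1.5) with the
  pentagon copy as a pure-noise item (&beta; = 0).
- **secondary** — signal concentrated in temporal orientation and
  calculation (&beta; = 1.8); six items are pure noise (&beta; = 0),
  giving this stratum its characteristic interference-heavy profile.
- **university** — calculation (&beta; = 2.0) and execution (&beta; = 1.5)
  carry the signal; orientation/memory/naming items are easy
  (&alpha; = 3) and uninformative (&beta; = 0), so controls sit safely
  above the cutoff and false positives are rare.

All &alpha;/&beta; values are package defaults chosen once for realism —
conventional-cutoff accuracies land in the 70-80% range with AUCs around
0.8-0.9, and the false-positive burden concentrates in the illiterate
stratum — not estimates from any dataset. Negative &beta; (anti-signal) is
accepted with a warning for users who want adversarial items; the
template uses &beta; = 0 for interference.

What the generator does **not** emulate: ceiling effects from compensation
in highly educated cases, differential item functioning beyond the
two-parameter logistic, missing data, rater effects, and any calibration
to real norms. Consequently, passing tests demonstrate that the pipeline
recovers planted structure and honours its arithmetic contracts — not that
the packaged weight constants are optimal for real populations. In
particular, the published thresholds T were calibrated on clinical data;
applied to synthetic cohorts they are comparatively lenient (T/60 lies
below cutoff/30 for every group), so on template data weighting mainly
removes false positives, at some sensitivity cost in the high-education
strata.

## Numerical choices

- **Determinism.** Every stochastic step (simulation, fold shuffling,
  bootstrap) runs under an explicit integer seed and restores the caller's
  RNG state. Identical config + seed reproduces artifacts byte-for-byte.
- **Tie-breaks.** Grid search returns the first maximiser in C-major,
  then gamma order.
- **Frozen hyperparameters in ablation.** (C, gamma) and the fold
  assignment are frozen at the baseline optimum during deletions, so
  &Delta; isolates the feature's removal from search and resampling
  noise; `research_per_deletion = TRUE` re-enables the full search per
  deletion.
- **Boundary conventions.** Total-score cutoffs use &le; (a score equal
  to the cutoff is impaired); the weighted rule uses S &lt; T (S = T is
  normal); category thresholds are strict, so &Delta; = &minus;1.0 or
  +0.5 exactly is neutral.
- **Degenerate inputs.** Single-class truth flags sensitivity or
  specificity as `NA` rather than silently reporting zero; a single-class
  training fold is an error; a constant feature gets unit scale instead
  of dividing by zero; an empty cohort round-trips as a header-only CSV.
- **Lenient versus strict reading.** Invalid rows are excluded and
  counted by reason (missing first, then range, group, label), and the
  exclusion ledger must reconcile exactly; `strict = TRUE` aborts on the
  first bad row instead.

The test suite exercises the stochastic properties at deliberately modest
problem sizes — single-stratum cohorts of 100-400 subjects and 5-20
seeded replicates per property (20 replicates at n = 300 for the
planted-item recovery and chance-level checks) — sizes at which each
property is already stable while the whole suite stays quick to run.

## Limitations

- The category-to-weight rule is one defensible mapping of contribution
  profiles to {1, 2, 3}; nothing in the framework forbids continuous
  weights, but integer weights are what keep the score clinically
  interpretable, and learning weights inside the SVM margin is out of
  scope.
- Per-stratum sample sizes below roughly 20 per class make 5-fold CV
  accuracy too noisy for stable ablation categories; the warning signs
  are fold accuracies spanning tens of percentage points.
- The exact McNemar test conditions on discordant pairs only; with very
  few discordant subjects its p-value is coarse. The bootstrap
  alternative trades exactness for a smoother statistic.
- AUC is computed from the scoring rule (total score before, S after),
  not from SVM decision values, so the before/after AUC contrast compares
  scoring rules, not classifiers.
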