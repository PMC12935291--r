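# mmsedw — education-stratified dynamic weighting for MMSE screening

The Mini-Mental State Examination (MMSE) is a 30-point, 11-subitem
screening test for cognitive impairment. Its subitems do not carry equal
information in every population: literacy-loaded tasks (reading, writing,
serial sevens, pentagon copying) inflate false-positive screens among
adults with little schooling, while highly educated adults compensate on
easy items and slip past the cutoff. Education-adjusted *total-score*
cutoffs shift the threshold but still weight every subitem equally.

`mmsedw` is for researchers in cognitive screening and psychometrics who
want an item-level, education-stratified treatment instead. Per education
stratum (illiterate / primary / secondary / university) it:

1. trains an RBF-kernel SVM on the 11 raw item scores with stratified
   5-fold cross-validation and a grid search over
   `C ∈ {0.1, 1, 5, 10, 100} × γ ∈ {0.001, 0.01, 0.1, 1}`;
2. quantifies each subitem's contribution by deletion:
   `Δᵢ = Accuracy_postdeletion − Accuracy_baseline` (percentage points,
   same folds, same hyperparameters), categorising items as **critical**
   (`Δ < −1.0`), **interference** (`Δ > +0.5`) or neutral;
3. maps contribution categories to integer weights (critical → 3,
   neutral → 2, interference → 1), or uses the packaged published
   education-specific weight tables;
4. scores subjects as `S = Σᵢ vᵢ·wᵢ`, rescaled by `60 / max_raw` so the
   maximal response scores exactly 60 in every group, and classifies
   `S < T` as impaired with group thresholds `T = 30/31/32/33`;
5. evaluates accuracy, sensitivity, specificity and rank-based AUC before
   (conventional cutoffs: illiterate ≤17, primary ≤20, secondary ≤22,
   university ≤23) versus after weighting, with an exact McNemar test and
   a per-group false-positive/false-negative fairness report.

A latent-severity synthetic cohort generator (`simulate_cohort()`) makes
the whole method testable without clinical data.

## Worked example

```r
library(mmsedw)
library(dplyr)

cohort <- simulate_cohort(cohort_template(seed = 42))
ill <- filter(cohort, education_group == "illiterate")

fit <- svm_grid_search(ill, cv_config(seed = 42))
glance(fit)
#>   group          C gamma mean_accuracy n_folds     n
#> 1 illiterate    10  0.01          83.5       5   108

abl <- ablate_items(ill, cv_config(seed = 42), fit = fit)
abl
#> Item-deletion analysis [illiterate]: baseline 83.46% (C=10, gamma=0.01)
#>    group      item                  post_accuracy   delta category
#>  1 illiterate time_orientation               83.5  0.0433 neutral
#>  2 illiterate space_orientation              76.1 -7.40   critical
#>  3 illiterate immediate_memory               79.6 -3.85   critical
#>  4 illiterate attention_calculation          79.7 -3.77   critical
#>  ...
```

The template generator plants its illiterate-stratum signal in spatial
orientation and immediate memory, and the deletion analysis recovers
exactly that: removing spatial orientation costs 7.4 accuracy points
(critical), while items like naming and delayed memory are neutral
(Δ ≈ 0). `derive_weights(abl)` turns the profile into a 3/2/1 weight
scheme; `published_weights()` gives the packaged calibrated tables
instead (raw weighted maxima 60/60/59/57, all normalising to a 60-point
ceiling).

```r
fairness_report(cohort)
#>   group      fpr_before fpr_after fpr_change fnr_before fnr_after fnr_change
#> 1 illiterate      12.5       4.17      -8.33       31.7      43.3       11.7
#> 2 primary          0         0          0          47.2      71.7       24.5
#> 3 secondary        7.82      0         -7.82       44.9      92.4       47.6
#> 4 university       3.10      0         -3.10       52.8     100         47.2
```

Under the conventional cutoffs, 12.5% of cognitively normal illiterate
subjects screen as impaired; weighted scoring cuts that to 4.2%
(`fpr_change = −8.33` points) — the fairness outcome the method targets.
The sensitivity cost visible in the high-education strata reflects the
packaged thresholds being calibrated for clinical, not synthetic, score
distributions (see the methods vignette).

The full pipeline — simulate or read a cohort, fit, ablate, weight,
score, evaluate — runs end to end with
`run_pipeline(list(synthetic = list(seed = 1), weighting = "published", out_dir = "run1", seed = 1))`,
which writes every artifact (cohort CSV, fit/ablation/evaluation JSON,
contribution-matrix CSV, fairness CSV) plus a manifest, and reproduces
byte-identical outputs under the same config and seed.

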