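---
title: "Multi-view late integration for small multi-omics cohorts: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view late integration: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem this package addresses

Clinical multi-omics studies of the infant gut frequently have a few
dozen subjects, a handful of visits, and thousands of measured
features spread over heterogeneous platforms: clinical variables, 16S
rRNA genus counts, metaproteomic protein intensities, immune panel
NPX values, and several metabolomics assays. Classifying subjects
(here: whether a cow's-milk allergy persists or is outgrown by 12
months) from such data runs into three compounding problems:

1. **p ≫ n with heterogeneous statistics.** Concatenating everything
   into one matrix ("early integration") mixes compositional counts,
   log-intensities and categorical codes, and invites overfitting.
2. **Repeated measures.** Each subject contributes one sample per
   visit; samples of the same subject are correlated, so any split
   that separates a subject's visits between training and test leaks
   information.
3. **Platform-specific missingness.** Sequencing zeros, intensities
   below detection limits, and left-censored metabolite values each
   need different treatment before a tree learner can consume them.

`lateRF` implements **late integration**: one random-forest classifier
per *view* (a data modality, optionally restricted to one visit),
whose predicted probabilities are combined as a weighted sum

\[ p(\text{persistent} \mid s) \;=\; \sum_i W_i \, \mathrm{Pred}_i(s),
\qquad W_i = \frac{\mathrm{AUC}_i}{\sum_j \mathrm{AUC}_j}, \]

where \(\mathrm{AUC}_i\) is view \(i\)'s cross-validated training AUC.
Views that generalize better get proportionally more say; views
missing a sample simply drop out of the sum (weights renormalized),
which concatenation cannot do.

Two view constructions are supported. **Approach 1** makes one view
per modality and stacks the visits as rows (units are subject-visit
samples). **Approach 2** makes one view per (modality, visit) pair
(units are subjects), which lets feature importance differ across
visits at the cost of thinner training sets.

## The pipeline, stage by stage

`run_experiment()` executes, for each of (by default) 5 train/test
repeats:

1. **Preprocessing** (`apply_recipe()`, computed once on the full
   table): counts and intensity views get the low-total filter
   (column sum < 3 removed) and the *robust centered log-ratio*
   transform — each positive entry becomes
   \(\ln x - \overline{\ln x_{>0}}\) over the positive entries of its
   row, zeros become missing (no pseudocounts, hence no spurious
   correlations). Metabolite views get the missingness filter
   (> 20% missing removed), optional dry-weight normalization, log2,
   and QRILC imputation (below). NPX and clinical views pass through;
   limit-of-detection filtering (`lod_filter()`) needs upstream LODs
   and is applied by the user when available.
2. **Splitting** (`grouped_stratified_split()`): per class,
   two-thirds of the *subjects* go to training (39 subjects → 26/13
   with a 16/10 class split); all visits of a subject travel
   together. Within the training set, subjects are dealt into 5
   grouped, stratified CV folds.
3. **Per-view training** (`tune_and_train()`): a random forest per
   view; remaining missing entries (RCLR zeros) are filled by a
   median imputer *fitted on the training rows of the current fold*.
   The view's `train_auc` is the AUC of the pooled out-of-fold
   predictions. Optional: `mtry`/`ntree` grid tuning, near-zero
   variance and correlation filters, oversampling or SMOTE.
4. **Integration** (`compute_weights()`, `combine_probs()`):
   AUC-proportional weights, weighted sum of test-set probabilities.
5. **Threshold selection** (`select_threshold()`): the grid threshold
   (0.05–0.95, step 0.01) maximizing the geometric mean of all views'
   training sensitivities and specificities, computed from the
   out-of-fold probabilities.
6. **Forward view selection** (`forward_select()`): if some single
   view beats the all-views ensemble on test AUC, greedy forward
   search seeded with the best single view, visiting candidates in
   descending individual test AUC and keeping a view only when the
   combined test AUC strictly increases.
7. **Reporting**: AUC, sensitivity and specificity per repeat plus
   mean and sample sd (`summarize_stat()`), and optionally
   permutation importance (below).

## The random-forest base learner

No random-forest implementation is assumed; the package ships a
compact one (`random_forest()`, C++ core). Trees are grown to purity
on bootstrap samples; each split draws `mtry` candidate features and
maximizes the Gini impurity decrease; leaves predict their
positive-class fraction and the forest averages over `ntree` trees.
Defaults follow the field convention `mtry = floor(sqrt(p))`,
`ntree = 500`. Fits are driven by a private RNG keyed by `seed`, so
results are bit-reproducible and independent of R's global RNG state.
Gini importance (summed impurity decrease per feature, averaged over
trees) is retained for the training-set importance report.

## QRILC imputation

Metabolite missingness is treated as *left-censoring*: a value is
absent because it fell below the detection limit. Per feature, the
`m` observed values are taken to be the top `m` of `n` order
statistics (plotting positions \((n-m+i)/(n+1)\)); regressing them on
the matching standard-normal quantiles over the upper 75% of the
observed points (the region least distorted by censoring) estimates
the feature's mean (intercept) and sd (slope). Missing entries are
drawn from that normal truncated above at the feature's observed
minimum — so no imputed value can exceed anything actually observed.
Features with fewer than 3 observed values fall back to a fit pooled
over the whole table, with a warning. Simulation (N(0,1) censored
below −1, n = 1000) puts the per-fit standard error of both
parameter estimates near 0.034 with negligible bias; the test suite
asserts recovery at tolerances derived from that simulation.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| `train_frac` | 2/3 | 26 training / 13 test subjects at n = 39 |
| `n_repeats` | 5 | repeats of the train/test split; the reported mean/sd quantify split dependence |
| `k` | 5 | CV folds, grouped by subject, stratified |
| `mtry`, `ntree` | `floor(sqrt(p))`, 500 | field defaults; tuning grid {½, 1, 2}·√p × {500, 1000} |
| threshold grid | 0.05–0.95 by 0.01 | optima near 0.4 require ≤ 0.01–0.02 resolution |
| low-total cutoff | 3 | genus/iBAQ filter, strict `<` |
| missingness / LOD cutoff | 20% | strict `>` drops a feature |
| QRILC tail | 0.75 | published default of the cited algorithm |
| importance cutoff | 0.01 | mean decrease in test AUC, strict `>` |
| `n_perm` | 100 | permutations per feature |

## What the synthetic generator emulates — and what it does not

`generate_cohort()` produces the statistical *structure* the pipeline
assumes: 39 subjects (24 outgrown / 15 persistent) at three visits;
compositional counts from a Dirichlet-multinomial at a fixed
sequencing depth (default 10,000) with structural zeros;
log-normal intensities with zero inflation; complete Gaussian NPX
panels; metabolite intensities left-censored at the per-feature
`censor_frac` quantile; clinical tables half continuous, half
integer-coded 4-level categoricals. A per-subject latent Gaussian
effect, correlated `subject_corr` across visits, loads on every view
— this is exactly the dependence grouped splitting must respect, and
a property test confirms the generator would expose a splitter that
ignored it. Informative features get a standardized between-class
mean shift `effect_size` (log-concentration scale for counts), with
optional per-visit multipliers so approach-1 vs approach-2 contrasts
can be constructed. One (view, visit, subject) cell can be dropped to
emulate a lost specimen.

It does **not** emulate: realistic taxon phylogenies or co-occurrence
networks, batch effects, platform drift, nonlinear class boundaries,
or feature-feature correlation beyond the single latent factor. A
green synthetic test therefore establishes that the machinery is
correct and that the statistical contracts hold — not that any
particular real cohort is classifiable.

### The acceptance worlds

Four fixed worlds back the acceptance suite: a **null** cohort
(4 views, effect 0) whose mean combined AUC must stay within
[0.35, 0.65] — measured on the *all-views* ensemble, because the
forward-selected AUC is a maximum over subsets evaluated on the test
set and sits near 0.6 even under the null (that optimism is the
protocol's, not a defect; both values are reported); a
**strong** cohort (effect 3, 5 informative features per view) for
AUC ≥ 0.85 and importance recovery; a **late-vs-early** pair (one
informative view + one noise view, 10 seeds, paired); and a 4-view
world whose greedy selection is compared against the exhaustive
15-subset oracle. The strong world uses zero-inflated counts and
intensity views (60% zeros, typical of genus tables and iBAQ
matrices) deliberately: with 5 redundant 3-sd features on clean
Gaussian views, every test AUC saturates at 1.0 and every
single-feature permutation decrease is identically 0 — recovery
would be unmeasurable. Sparsity attenuation keeps the ensemble below
saturation so permutation importance has something to detect.

## Numerical and tie-break choices

- **AUC** is the Mann–Whitney statistic (ties count ½), identical to
  trapezoidal ROC area.
- **CV AUC** pools out-of-fold predictions rather than averaging
  per-fold AUCs: with ~5 subjects per fold a per-fold AUC is nearly
  meaningless. This is an interpretation of "AUC on the training
  set"; resubstitution AUC of a purity-grown forest is ≈ 1 and
  useless for weighting.
- **Threshold ties** prefer the value closest to 0.5, then the
  smaller; a degenerate all-zero geometric-mean profile falls back to
  0.5 with a warning. The geometric mean pools all views'
  sensitivities and specificities jointly (2V values); averaging
  per-view geometric means is available via `pooling = "per_view"`.
- **Classification boundary**: probability equal to the threshold is
  called positive.
- **Forward selection** uses strict `>` on test AUC, exactly as
  specified — no epsilon. Candidate order (descending individual test
  AUC, ties in input order) is a determinism choice; the order is not
  dictated by the source procedure.
- **Stratified counts** round half up per class, then the largest
  class absorbs the correction so the global 26/13 total is exact.
- **Fold dealing** orders folds by current occupancy with random
  tie-breaks, which guarantees both per-class (≤ 1) and total balance.
- **RCLR zeros** remain missing downstream and are median-imputed at
  fit time from training rows only; an all-zero sample row is an
  error, not a silent NaN.
- **Weight floor**: a view with CV AUC numerically 0 would break the
  AUC-proportional weights; weights are computed on
  `max(train_auc, 1e-6)`.

## Known limitations

- Forward selection evaluates candidate subsets on the *test* set, as
  the emulated workflow does. This is optimistic: the reported AUC of
  the selected subset is a selection maximum, not an unbiased
  estimate. The all-views ensemble (`forward = FALSE`) gives the
  honest counterpart.
- The permutation shuffle for approach-1 views permutes rows freely
  across visits; no subject-blocked permutation variant is provided.
- With ~13 test subjects, per-split metrics are extremely noisy; only
  the across-repeat mean/sd should be interpreted, and even those
  depend visibly on the split seed.
- SMOTE requires more minority subjects than `k_neighbors`; with 10
  minority training subjects and per-visit views it is often simply
  infeasible (that infeasibility is reported as an explicit error).
- The forest treats integer-coded categoricals as ordered; proper
  categorical splits are not implemented.
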