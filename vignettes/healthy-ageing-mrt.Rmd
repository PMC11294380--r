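---
title: "Healthy-ageing indices and multivariate regression trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Healthy-ageing indices and multivariate regression trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agetree)
library(dplyr)
```

## The analysis this package implements

Large ageing surveys record health not as a single score but as dozens of
coded items: chronic-disease diagnoses, difficulties with activities of daily
living (ADL/IADL), affect and life-satisfaction frequencies, cognitive test
components, and social-activity frequencies. `agetree` condenses these into
five composite healthy-ageing indices — **physical**, **functional**,
**mental**, **cognition** and **social**, always in that canonical order —
and then asks which demographic, socio-economic and behavioural factors
jointly partition respondents into groups with distinct profiles across all
five indices at once. The partitioning tool is a **multivariate regression
tree** (MRT, in the tradition of De'ath's extension of CART to multiple
continuous responses): greedy binary recursive splitting of respondents on
ordinal coded predictors, where a split's quality is the mean squared error
summed over the five indices in the resulting children.

A typical run is

```{r, eval = FALSE}
cohort <- generate_survey(synth_config(n = 20000, seed = 1)) |>
  apply_filters(min_age = 45)
idx <- build_all_indices(cohort$data)
model_data <- left_join(cohort$data, idx, by = "id")
fits <- fit_age_stratified(model_data, cv = TRUE, seed = 1)
```

## Eligibility cascade

`apply_filters()` removes, in this fixed order: respondents below the
minimum age (45 by default); respondents without biomarker data
(`biomarker_available = 0`); respondents with a missing value in *any*
analysis variable (predictor or indicator item named in the codebook —
columns outside the codebook never trigger removal, and no imputation is
attempted). Each stage is counted against the survivors of the previous
stage, so the `exclusion_ledger` identity

    final_n = initial_n - removed_under_age - removed_no_biomarker - removed_missing

holds exactly and a record failing several criteria is counted once, at the
earliest stage. The cascade order matters only for the attribution of
removals, not for the final sample. "Missing" here means item-level
missingness on model variables; whole-interview non-response is
indistinguishable from it in a rectangular extract, and the filter treats
both identically.

## Index construction

Every indicator item is first recoded so that **higher = healthier**:
disease and ADL/IADL difficulty items are flipped (`1 - code`), negative-
affect frequency items (depression, loneliness, fear, trouble concentrating,
feeling bothered, everything-is-an-effort, fatigue) are reversed on their
0–3 scale, while positively worded items (satisfaction, hopefulness,
happiness) and all cognition and social-activity items keep their direction.
The per-item reverse flags are visible in `index_definitions()`.

Each recoded item is min–max scaled,
`(x - min) / (max - min)`, summed within its dimension, and the five sums
are centred to mean zero over the **full filtered sample**. Two choices
deserve comment:

* **Scaling bounds.** By default the bounds are the *theoretical* code range
  from the codebook (`0 .. n_codes - 1`), which makes an index value mean
  the same thing in any sample. `bounds = "empirical"` switches to the
  observed min/max per item; under empirical bounds a constant item carries
  no information and is dropped with a warning (contributing 0) rather than
  aborting on the degenerate `max = min` case.
* **Centering population.** Zero-mean normalisation happens once, globally,
  *before* any age stratification. Age-group means are therefore signed and
  comparable: the youngest group typically sits above zero and the oldest
  below, which is exactly the descriptive pattern `age_group_means()`
  reports.

Items are summed with equal weight; there is deliberately no factor
analysis, item-response modelling or survey weighting here.

## The multivariate regression tree

A node holding $N$ respondents with index values $y_{ij}$
($j = 1,\dots,5$) has impurity

$$\mathrm{MSE} = \frac{1}{N} \sum_{i=1}^{N} \sum_{j=1}^{5}
  (y_{ij} - \bar y_j)^2,$$

with $\bar y_j$ the within-node mean. A candidate split sends rows with
feature code $\le$ threshold to the left child and is scored by the
child impurities weighted by the child fractions,

$$\mathrm{Weighted\ MSE} = \sum_{j=1}^{5}
  \left( \tfrac{N_L}{N} \, \mathrm{MSE}_{L,j}
       + \tfrac{N_R}{N} \, \mathrm{MSE}_{R,j} \right).$$

`weighted_split_mse(criterion = "as_printed")` additionally preserves, for
auditability, a variant that weights both children by $N_L/N$; its weights
do not sum to one, so the corrected form above is the default everywhere.

All predictors are treated as **ordinal integer codes** and candidate
thresholds are the midpoints between consecutive *observed* codes — for a
wealth quintile coded 0–4 a split at 2.5 groups poorest/poorer/middle
against richer/richest. There is no subset search over nominal categories;
for genuinely unordered predictors with more than two codes the tree can
only express contiguous groupings, a known consequence of this encoding.

Numerical conventions, chosen for bit-reproducible trees across platforms:

* node means and impurities use two-pass accumulation in double precision;
* a split is accepted only if it reduces the parent impurity by more than
  `tol = 1e-12`;
* ties within `tol` resolve to the feature earliest in codebook order, then
  the smallest threshold;
* growth is depth-first, left child first, so node ids are preorder.

Stopping is controlled by `max_depth`, `min_samples_split` (default 20) and
`min_samples_leaf` (default 10); the defaults encode "stop when nodes get
very small" at a scale sensible for survey data with tens of thousands of
rows, and both are overridable. A depth-3 tree whose every node admits a
split has exactly $2^3 = 8$ leaves, the layout used for the stratified
figures this package renders.

## Depth selection by cross-validation

`select_depth_cv()` shuffles rows once with the supplied seed, deals them
into `k` folds of as-equal-as-possible size (plain, unstratified k-fold),
and scores each candidate depth by the held-out summed MSE averaged over
folds; the chosen depth minimises that curve, with ties going to the
smaller depth. Depth is the only complexity parameter tuned — there is no
cost-complexity pruning path, and no surrogate splits or missing-value
routing anywhere (filtered data cannot contain missing predictors).

One implementation note: a tree grown with depth cap $D$ and *truncated* to
depth $d \le D$ is identical to the tree grown with cap $d$, because greedy
growth never looks ahead and the size-based stopping rules are local. The
CV loop therefore grows one tree per fold at the largest candidate depth
and evaluates all depths by truncated prediction; this is an exact
optimisation, not an approximation, and it is property-tested.

When a held-out test set is wanted in addition to CV, `split_train_test()`
provides a seeded 80/20 partition (the fraction is an argument); CV is then
applied to the training part.

`fit_age_stratified()` repeats the whole procedure independently in the
age strata `[45, 60)`, `[60, 75)`, `[75, ∞)` and on the full sample
(`"all"`), skipping empty strata with a warning.

## What the synthetic generator emulates — and what it does not

`generate_survey()` produces coded tables shaped like a large ageing-survey
wave: 19 predictors with the survey's category structure, 48 indicator
items, an age column, a biomarker-availability flag, and cell-level
missingness. Its defaults are fixed once and treated as the study
conditions of the package's tests:

* the under-45 fraction (9.26%), biomarker non-response (8.84% of the
  remainder) and a per-cell item missing rate of 1.7e-4 (so that roughly
  1.2% of rows lose a cell across the 67 analysis columns) mirror the
  relative sizes of the three exclusion stages in a 72,250-person wave;
* indicator items are drawn per dimension as `Binomial(K - 1, p)` healthy
  scores mapped back to the raw coding direction, with baseline `p` per
  dimension (`default_base_p()`), a per-year age tilt
  (`default_age_effects()`, negative for every dimension and smallest for
  mental health so that its stratum mean crosses zero last), and planted
  threshold effects (`default_planted_effects()`, dominated by years of
  education) acting on `p` *before* any index arithmetic — recovery tests
  therefore exercise the entire recode/scale/sum/centre pipeline, not just
  the tree;
* marginal distributions are uniform or mildly skewed (education strongly
  right-skewed, binary amenities imbalanced); the generator makes no
  attempt to match real prevalences, state-level heterogeneity or the
  multistage sample design of an actual survey.

Consequently, a passing test suite shows that the pipeline's *mechanics*
are correct under known structure; it says nothing about substantive
findings in restricted microdata, whose leaf values are not reproducible
here and are not targeted.

`synth_tree_benchmark()` is the sharper instrument for the tree itself: four
uniformly coded predictors, five continuous targets whose means follow a
true depth-2 partition (root on education at 4.5, then safety on one side
and wealth on the other, mean separations of 0.3–1.2) with Gaussian noise
of sd 0.25 — "small" relative to those separations, so that depths 0–1
underfit grossly while depths 3–5 can only fit noise. At n = 2000 and
k = 5 this makes depth-2 recovery the overwhelmingly likely CV outcome,
which the acceptance suite checks across 20 replicate seeds.

## Problem sizes and determinism

The shipped tests run the cascade on a planted 72,250-row wave, tree and
index checks on 1,500–4,000 rows, the split-search oracle on 200 random
instances of up to 40 rows and 4 features, and the depth-recovery study on
20 replicates of n = 2000 — sizes chosen so that every property is
exercised at survey-like scale while the whole suite stays quick on a
single core. All randomness flows through explicit integer seeds (one root
seed per generator call, with a documented draw order), and the end-to-end
pipeline is checksum-reproducible: two runs of `run_pipeline()` with the
same configuration produce byte-identical artifacts.

## Known limitations

* Ordinal midpoint splits cannot express non-contiguous groupings of
  nominal codes (see above).
* The tree identifies partitions, not causal effects; leaf mean vectors are
  group averages.
* Survey design weights are intentionally ignored by the model; all
  respondents count equally.
* Rendering (`render_tree()`) emits Graphviz DOT and indented text; leaves
  are labelled `leaf` (figures derived from such models sometimes call
  them "decision nodes" or "outputs"). Node fill shade is a linear
  grayscale on the *rank* of the node's squared error within its tree,
  darkest for the lowest squared error — a qualitative convention, not a
  calibrated palette.
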