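---
title: "Methods: SHAP-guided ensemble ranking and optimized forward selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SHAP-guided ensemble ranking and optimized forward selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapsel)
```

## The problem

Clinical tabular classifiers — here framed around binary coronary artery
disease (CAD) diagnosis — are routinely trained on a few dozen mixed
binary/categorical/continuous features, many of which are redundant or
uninformative. shapsel implements a hybrid feature-selection procedure in
two phases:

1. **Ensemble Shapley ranking.** Three heterogeneous classifiers
   (gradient-boosted trees, a random forest, and an RBF support-vector
   machine) are each fitted on the full feature set. For each model the
   Shapley value $\varphi_i^{(j)}$ of feature $i$ on instance $j$ is
   computed against a background-marginalised value function, and global
   importance is the mean absolute attribution
   $I_i = \frac{1}{n}\sum_j |\varphi_i^{(j)}|$. Each model's importances
   are converted to ranks (1 = most important); the three rank columns
   form the feature rank table (FRT), and their arithmetic mean, sorted
   ascending, the average rank table (ART).
2. **Optimized forward selection.** A wrapper walks the ART order once:
   the subset is seeded with the top-ranked feature, each next-ranked
   feature is kept only if mean stratified-CV accuracy strictly improves,
   and finally the seed feature itself is dropped if that strictly
   improves the score. This needs at most $M + 1$ subset evaluations,
   versus $O(M^2)$ for classic sequential forward selection.

## The value function and the two estimators

A coalition $S$ is scored interventionally:
$v(S) = \mathbb{E}_{b \sim B}\, f(x_S, b_{\bar S})$, the model's
positive-class probability with coalition features fixed to the instance
and the rest drawn from a background sample $B$. $v(\varnothing)$ is the
base value $\varphi_0$; $v(F)$ is the probability on the instance itself.

* `exact_shapley()` enumerates all $2^M$ coalitions and applies the
  subset weights $|S|!(M-|S|-1)!/M!$ directly. It is guarded at
  $M \le 15$ (32,768 coalitions times a background of at most 100 rows
  stays desk-scale) and satisfies efficiency
  ($\sum_i \varphi_i + \varphi_0 = f(x)$) to $10^{-9}$.
* `sampled_shapley()` is a KernelSHAP-style estimator: coalitions are
  drawn in complementary pairs from the kernel distribution
  $p(|S|) \propto (M-1)/(|S|(M-|S|))$, duplicates collapse into frequency
  weights, and a weighted least-squares regression with the efficiency
  constraint eliminated into the last coefficient yields all instances'
  attributions from one shared design factorisation. When
  `n_coalitions >= 2^M - 2` the full non-trivial coalition set is used
  with exact kernel weights, which reproduces the enumeration estimator
  to numerical precision — this equivalence is a standing test.

The model output attributed is always the positive-class probability: it
is the one output comparable across all seven supported classifier
families and the quantity the diagnostic metrics operate on. Probability
outputs also keep attributions on a common scale when ranks from the
three models are averaged.

Attribution of tree models is *not* delegated to the tree-path algorithm
built into gradient-boosting libraries: that algorithm conditions on tree
traversal paths rather than on an explicit background sample, so its
values differ from the interventional definition used here and would fail
the enumeration-oracle equivalence. All three ranking models therefore go
through the same in-package sampler, which also keeps the three rank
columns methodologically homogeneous.

## Preprocessing and the leakage contract

* Cases with any missing value are excluded (no imputation is offered).
* Categorical features are label-encoded with levels ordered
  lexicographically on their string form — deterministic and platform
  independent.
* Min–max normalisation $x' = (x - \min X)/(\max X - \min X)$ is fitted
  on training data only and applied as a pure affine map: held-out values
  may leave $[0,1]$ and are never clipped. A constant training feature
  maps to 0.
* SMOTE raises the minority class to the majority count by interpolating
  between a minority anchor and one of its `k_neighbors = 5` nearest
  minority neighbours (Euclidean, on the normalised representation), with
  the interpolation weight uniform on $[0,1)$ and anchors cycled
  round-robin. Binary features are interpolated like any other column
  (plain SMOTE, no rounding).

Inside every cross-validation fold the pipeline is: restrict columns,
fit min–max bounds on the training part, normalise both parts, SMOTE the
training part only, fit, score the held-out fold. SMOTE runs after
normalisation so that neighbour distances weigh features comparably.
Synthetic rows are tagged, and a standing test asserts they never appear
in a test fold.

For the ranking phase (which fits on the full dataset rather than within
folds) a switch applies one round of SMOTE before fitting when the
majority/minority ratio exceeds 1.5 — markedly imbalanced cohorts (e.g.
a 216:87 split, ratio 2.48) are balanced, near-balanced ones are not.
Attributions are always computed on original, pre-SMOTE cases.

## Ranking conventions

Ranks are integers $1..M$; ties in importance are broken by the dataset's
original column order (stable sort), and ties in average rank are broken
the same way. This is the only tie rule consistent with the reference
Cleveland rank tables shipped in `inst/extdata`, where `ca` precedes
`thal` and `sex` precedes `slope` within equal-average groups, matching
that dataset's column order. Averages are exported to six decimals.

## Selection conventions

* The improvement metric is mean CV accuracy — the headline diagnostic
  metric of this literature; precision/sensitivity/specificity/F1/AUC are
  reported on the final subset but do not drive acceptance.
* Strict improvement uses an absolute tolerance of $10^{-12}$; ties
  reject the candidate, preferring smaller subsets.
* One fixed fold plan is reused for every candidate within a run, so all
  comparisons are paired; re-drawing folds per candidate would inflate
  the variance of accept/reject decisions.
* Hyperparameters stay fixed for the whole selection run (the tuned
  presets of `preset_hyperparameters()` by default); `grid_search()`, if
  used, runs once on the full feature set beforehand. Re-tuning per
  candidate would multiply the wrapper's cost by the grid size.
* Only the top-ranked seed feature gets the final removal check; the
  other retained features were each admitted on a measured improvement.

## Classifier backends

Model fitting is delegated to established libraries (xgboost, ranger,
e1071, rpart, `stats::glm`, nnet); shapsel standardises them behind a
matrix-in/probability-out interface. Two mappings are worth noting: the
multilayer perceptron uses nnet's single hidden layer, so two-layer
preset sizes map to the first layer only; and logistic regression is the
plain unpenalised GLM. k-nearest-neighbour prediction is implemented
in-package (a few lines) because the Manhattan metric of one preset is
not available in the standard backend.

## The synthetic generator

`synthesize_dataset()` emulates the structure of small clinical cohorts:
informative features are standard normal and drive the label through a
logistic link whose intercept is solved by bisection (to $10^{-6}$) so
the expected positive fraction equals the requested imbalance; redundant
features are $\rho \cdot \text{parent} + \sqrt{1-\rho^2}\,\varepsilon$
copies; noise features are independent; and a chosen fraction of columns
is dichotomised at its median to mimic clinical yes/no indicators.
Gaussian noise on the linear predictor plays the role of label noise.
`make_cad_like_fixture()` wraps three presets matching the shapes of the
public CAD benchmarks (303×55 with a 216:87 split, 303×13, 270×13),
pinning class counts exactly by thresholding the noisy latent score at
its matching quantile.

The fixed planted-recovery condition used by the acceptance checks is
`planted_recovery_spec()`: $n = 600$, 4 informative features with effect
sizes (2.5, 2, 1.5, 1.5), 4 redundant copies at $\rho = 0.8$, 8 noise
features, 40% positives, label-noise SD 0.5, a quarter of columns
dichotomised. These values were fixed as the study condition before any
recovery measurement.

What the generator does **not** emulate: real covariance structure among
clinical measurements, measurement error, missingness mechanisms, or
site effects. Passing recovery tests therefore demonstrates that the
pipeline finds planted low-dimensional signal under realistic noise and
imbalance — not that it reproduces any particular cohort's published
accuracy, which requires the external benchmark data themselves.

## Numerical and scale choices

* Ranking-phase attribution defaults in `rank_features()`: at most 100
  explain instances and 50 background rows (both seeded subsamples), and
  `n_coalitions = min(2^M - 2, max(2M + 2, 8M))`. Global importance is a
  mean of $|\varphi|$ over instances, so a moderate instance subsample
  estimates it with small error relative to between-feature gaps; small
  $M$ automatically gets exact enumeration. `value_function_spec()`
  itself defaults to a background cap of 100 for single-instance
  explanation work.
* The test suite and the bundled acceptance script run the planted
  recovery at 20 and 5 seeded replicates respectively, and use 5–10 CV
  folds depending on the check; these sizes keep the whole suite at
  desk scale while leaving the binomial noise on recovery rates well
  below the pass margins.
* Degenerate metric ratios (0/0) are reported as 0 and flagged rather
  than thrown, so fold reports stay total.
* AUC is the midrank Mann–Whitney statistic; ties count one half.
* A degenerate sampled-coalition design (fewer distinct coalitions than
  features) is resampled with a derived seed and a warning.

## Known limitations

* Exact enumeration is infeasible above $M = 15$; sampled attributions
  carry Monte-Carlo error that the convergence tests bound only in
  expectation.
* The wrapper is greedy by construction: it cannot recover a feature
  rejected earlier whose value only emerges in combination with a
  later-accepted one, and the removal check covers the seed only.
* SMOTE interpolates encoded categoricals as if continuous; synthetic
  rows may carry fractional category values. This follows the plain
  SMOTE variant; a nominal-aware variant is out of scope.
* With near-constant features inside a fold, min–max normalisation can
  amplify noise (the affine map is fitted per fold by design).
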