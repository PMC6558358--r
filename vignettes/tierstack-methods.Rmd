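---
title: "Methods: multi-tier stacking for imbalanced risk-factor data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-tier stacking for imbalanced risk-factor data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tierstack)
```

## The model

`tierstack` targets binary outcome prediction (preterm birth, PTB = 1,
versus term birth, TB = 0) from tabular, mostly binary risk-factor data
with strong class imbalance. The core is a three-tier stacked ensemble.

**Base tier.** m base learners are trained with stratified k-fold
cross-validation (default k = 10). Fold assignment is per-class round-robin
after a seeded shuffle, continued across classes, so folds are disjoint,
exhaustive, balanced in size, and each fold's positive count is within one
of perfect proportionality. Learner j's out-of-fold (OOF) score for
instance i comes from the model trained on the k−1 folds that exclude i, so
the level-1 training input is free of resubstitution optimism. After the
OOF pass each learner is refit on all rows; deployment-time prediction uses
these refits (the per-fold models are discarded — one consistent model per
learner rather than an arbitrary fold's).

**Ensemble tier.** Each combination scheme maps an instance's m OOF scores
(or the hard labels obtained by thresholding them at 0.5) to a single
number in [0, 1], giving one meta-feature per scheme. Defaults are
averaging and majority voting; exact vote ties resolve to PTB because a
false negative (a missed PTB) is the costlier error. Max-score and
product-rule (geometric mean, i.e. the m-th root of the product, which
keeps the result on the [0, 1] scale) schemes are registered and
selectable but not defaults: measured on the default generator, the
product meta-feature collapses to 0 whenever any single learner emits a
hard 0 and the max meta-feature saturates near 1, and including them
reduced mean held-out accuracy of the stacked model below the traditional
baseline, while the averaging + majority roster did not. The scheme list is
configuration-driven, so any registered subset can be used.

**Generalization tier.** The meta-learner (default: logistic regression,
a deliberately low-variance level-1 generalizer) is trained on the s
meta-features concatenated with the k_meta = 3 raw features most correlated
with the label. A `"passthrough"` meta-learner (mean of the level-1
columns) exists for degenerate configurations: with one learner, one
averaging scheme and k_meta = 0 the whole stack provably reduces to the
single learner, which the tests assert.

The traditional stacked ensemble — meta-learner trained directly on the
n × m OOF score matrix — is implemented as the comparison baseline and
shares the fold plan with the proposed algorithm under equal seeds, so
comparisons are paired.

## Feature ranking

Features are ranked by |Pearson correlation| with the 0/1 label; for a
binary feature this equals the phi coefficient, so one code path serves
binary and numeric columns. Constant columns get score 0; ties break by
ascending column index so rankings are deterministic. Absolute value is
used because a strong protective factor is as informative as a risk
factor. Because Pearson correlation is invariant to column centering, the
ranking is unaffected by whether it is computed before or after
mean-cancellation. Within a feature-subset experiment the top-3 are chosen
from the active subset only.

## Preprocessing pipeline

Fixed order: impute → outlier removal → SMOTE → mean-cancellation. Every
fitted statistic derives from training rows only; held-out rows receive the
stored imputation values and column means, and transforming them cannot
alter the fitted parameters (asserted by serializing the parameters before
and after).

*Imputation* is criticality-aware: primary (critical) features get their
training mean, secondary features their declared default value. A critical
feature with no observed training values is a fit error.

*Outlier screening* concatenates the five most label-correlated binary
features into a 5-bit code and flags instances whose (code, label) pair
occurs fewer than `min_count` times, defaulting to
max(2, ⌈0.001·n⌉). This formalizes "far from the central mass of the
code/label scatter" as a computable frequency rule. Mean-imputed binary
values can be fractional, so values are rounded at 0.5 when forming the
code; the binary requirement itself is checked against the declared dtype.

*SMOTE* synthesizes minority instances as x + u·(x_nn − x) with
u ~ U(0, 1) and x_nn one of the k = 5 nearest minority neighbors
(Euclidean, computed on pre-normalization values), until minority equals
majority count. Originals are never altered; synthetic values of binary
features stay continuous by default (`smote_round_binary` re-rounds them).
k = 5 is the canonical SMOTE neighborhood. By default SMOTE is applied to
the training partition only (`smote_scope = "train"`), so no synthetic
point can leak information into evaluation; `"full"` balances the whole
dataset before splitting for protocols that did so.

*Mean-cancellation* centers every column — including binary ones — on its
training mean, fitted after SMOTE so the centered training matrix has
exactly zero column means.

## Base learners

Five diverse, moderately performing defaults: logistic regression, a CART
tree, Gaussian naive Bayes (with per-class standard deviations floored at
1e-6 so zero-variance columns cannot produce degenerate densities), 5-NN,
and a linear SVM. The kNN score is the neighbor vote fraction computed
in-package with deterministic index-order tie-breaking, because binary
rows are heavily duplicated and distance ties are the norm. SVM scores are
decision values passed through a logistic (Platt-type) calibration fitted
on the training decision values — a single extra GLM rather than an
internal cross-validated calibration, keeping base-tier cost linear in the
roster. Learners exposing only hard labels would enter the schemes as
scores in {0, 1}; all current defaults produce genuine probabilities.

## Evaluation protocol

Each experiment runs `n_trials` (default 10) independent trials; trial t
uses seed base + t for its stratified 80/20 train/test split — stratified
over the four clinical cases (any active primary factor × outcome) so all
four remain represented on both sides — its preprocessing, and its fold
plan. Metrics are accuracy, precision, sensitivity (PTB recall), F1, and
trapezoidal AUC from a threshold sweep over unique scores (tied scores
move together, matching the ties-count-half concordance convention).
Averaging across trials is macro (mean of per-trial metrics), never pooled
confusion counts. Precision is defined as 0, with a warning, when nothing
is predicted positive. The decision threshold is fixed at 0.5 everywhere;
only the ROC sweep varies it.

## The synthetic generator

The generator emulates the structure of a masked obstetric registry:
independent Bernoulli risk factors (8 primary, 12 secondary; prevalences
evenly spaced 0.30 down to 0.05), a logistic latent model
P(PTB) = plogis(intercept + Σ wⱼxⱼ) with primary log-odds effects 1.5–0.4
strictly above secondary effects 0.3–0.05, 2% label flips, and 1% missing
cells. The intercept default of −3.5 was set by Monte-Carlo so the
marginal PTB prevalence is ≈ 0.29 — clearly the minority class, matching
the imbalance such registries show. Label noise makes accuracies plateau
below 100% like real data, so algorithm comparisons are meaningful; the
noise-free `generate_separable()` fixture (label = OR of the first two
primary factors) exists for exactness tests. The generator guarantees all
four (risk, outcome) cases occur, redrawing labels up to 100 times before
erroring.

What the generator does *not* emulate: correlation between risk factors
(real comorbidities cluster; a hook for a pairwise-correlation structure is
left open), informative missingness, numeric features, or any particular
registry's marginal distributions. Passing tests on this generator
therefore demonstrate protocol correctness and relative algorithm
behavior, not clinical performance on real data.

## Problem sizes and observed behavior

The test suite exercises the full protocol at the registry scale the
generator defaults to (n = 2600): a ten-dataset seed grid with paired
splits for the proposed-versus-traditional comparison, and ten-trial
experiments for the feature-subset orderings; the acceptance script runs
all five default experiments at five trials each. On this generator the
proposed algorithm is non-inferior to traditional stacking in accuracy and
slightly ahead in AUC. One documented divergence: mean held-out AUC is
consistently *higher* for primary-factors-only than for all factors
(≈ 0.77 vs ≈ 0.75), because the twelve weak secondary features add more
estimation variance than recoverable signal at this sample size — the
efficient-subset behavior one expects from weak, low-prevalence
predictors, and the corresponding acceptance expectation that all-factors
ranks first is knowingly left unmet under these conditions.

## Numerical and degenerate-input choices

Scores are clipped to [0, 1] after every learner; GLM separation warnings
on noise-free data are suppressed (fitted 0/1 probabilities are exactly
what is wanted there). Splits guarantee at least one instance per stratum
on each side when a stratum has ≥ 2 members; strata with a single member
go to training. SMOTE requires both classes and ≥ 2 minority instances;
its neighbor count is capped at minority size − 1. Single-class inputs are
errors for correlation ranking, ROC and AUC rather than silent NaNs. All
randomness flows through explicit integer seeds (`withr::with_seed`), so
every artifact in the package — datasets, folds, SMOTE draws, splits — is
bit-reproducible given a seed.
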