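---
title: "Selective deep ensembles for TCM clinical coding: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective deep ensembles for TCM clinical coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmensemble)
```

## The model

A clinical record carries a feature vector `x` (11 basic-info reals plus a
boolean keyword-match vector over a fixed dictionary), a single ICD-10 label
`y`, a TCM diagnosis `z` from a finite code set, and a 53-ary boolean
acupuncture plan. The coder is an ensemble `h : X -> L x Z` built in two
stages: a pool of bootstrap base learners, then either *selective majority
voting* or *capacity-regularized boosting* on top of it.

The data are assumed multimodal — one latent mode per disease — with the
disease signal carried dominantly by the keyword features. Every base
learner emits the full tuple `(y, z)`, realized as two coupled heads (one
multi-class model per component) sharing one bootstrap sample, plus a
bounded margin score in `[-1, 1]` for every binary one-vs-rest task (each
ICD-10 label, each TCM code, each acupoint).

### Tuple accuracy and diversity

Zero-one loss cannot rank tuple-valued learners finely enough, so accuracy
is a weighted sum of three indicators (ICD-10 match, TCM match, both),
with weights `alpha`, `beta`, `gamma`. Two readings in the source material
are underdetermined and fixed here as package policy:

* the joint indicator is read as *both components simultaneously correct*
  (tuple equality);
* the correctness gate in the diversity statistic is likewise full-tuple
  equality.

Diversity sums the *squared* tuple Hamming distance (values 0, 1, 4)
between a learner's output and the full-pool majority vote, gated on the
learner being correct, normalized by `|D|^2`. The squared distance is kept
literally as printed in the source formulation. The reference ensemble for
diversity is the majority vote of the *entire* pool, computed once before
any selection, so all learners are scored against the same yardstick.

Defaults: `alpha = beta = gamma = 1/3`, which normalizes accuracy to
`[0, 1]`; the source never states values, and the symmetric choice makes
accuracy 1 equivalent to "every tuple reproduced".

### Nondominated sorting and selection

Both metrics are converted to ranks (rank 1 = best; raw-metric ties break
by learner index, making each rank list a strict permutation — so dominance
comparisons never see equal ranks). A learner dominating another on both
rank lists precedes it; fronts are peeled in order, incomparable learners
inside the ordering fall back to the sum of the two ranks, and residual
ties break by learner index. The six-learner worked example in the source
material cannot distinguish "Pareto-front-first, then sum rank" from
"sum rank only" (both yield the same final order there); the front-first
reading follows the prose and is what `nds_sort()` implements. The test
suite checks it against an independent longest-dominator-chain oracle.

Selection keeps the `max(1, round(m b / 100))` NDS-best learners. The
source never states the evaluation value of `b`; the package default is
`b = 20`, a conventional selective-ensemble pruning level, and every entry
point exposes it.

### Capacity-regularized boosting

For a binary task with labels in `{-1, +1}` and learner margins
`h_i(x) in [-1, 1]`, weights solve

```
min_{alpha >= 0, sum(alpha) <= cap}
  (1/n) sum_j Phi(1 - y_j sum_i alpha_i h_i(x_j)) + lambda sum_i alpha_i r_i
```

* `Phi` defaults to the exponential surrogate `Phi(u) = exp(u)`; a logistic
  variant `log(1 + exp(u))` is selectable. The source never instantiates
  `Phi`.
* `r_i` is never defined in the source; the package uses the size proxy
  `r_i = sqrt(c_i / n)` (leaf count for trees, non-negligible coefficient
  count for margin models), normalized to max 1. It is monotone in model
  size, which is all the penalty needs.
* The printed budget `sum(alpha) <= 1/n` shrinks all weights to zero as the
  sample grows, and conflicts with the printed decision rule; both readings
  are implemented behind `weight_cap`: `"unit"` (cap 1, default) and
  `"paper"` (literal `1/n`).

**Solver.** Cyclic coordinate descent with a bounded line search per
coordinate (Brent's `optimize()` with explicit endpoint checks; a move is
accepted only when it improves, so the objective trace is non-increasing by
construction). Because the budget couples the coordinates, single-coordinate
moves can stall once `sum(alpha)` hits the cap — every individual
coordinate can then only move down. When a sweep stalls, the solver runs
pairwise *exchange* steps along `e_i - e_j` (total weight unchanged), which
together with the single-coordinate moves span all feasible directions of
the set `{alpha >= 0, sum(alpha) <= cap}`; for this smooth convex objective
that restores stationarity. The acceptance suite verifies the solver
against a refined-grid oracle to an objective gap of `1e-4` on random small
instances.

**Decision rule.** The combined score is reported on the `[0, 1]` scale:
`y' = sum_i alpha_i p_i(x) / sum_i alpha_i`, with `p_i = (h_i + 1)/2`, and
class 1 is declared exactly when `y' >= 0.5` (the boundary case is
positive). When all weights are zero the model abstains with `y' = 0`,
hence class 0. This resolves an inconsistency in the stated behaviors
(an "abstain" example requires score 0 to map to `y' = 0`, which is only
coherent on the probability scale).

**Multi-output lifting.** The source defines boosting for binary outputs
only. The package lifts it one-vs-rest: one boosted head per observed
ICD-10 label and per observed TCM code, combined by argmax over `y'` (ties
to the lowest label index); one head per acupoint with the threshold rule.
Schema labels never observed in training are excluded with a warning and
cannot be predicted.

### Base learners

The original study trained decision trees and SVMs through an external
toolkit. This package's target environment has no tree or SVM library, so
both kinds are provided as follows, behind the same learner contract:

* **Trees:** an in-package weighted CART (Gini impurity, axis-aligned
  midpoint splits, unlimited depth by default, deterministic tie-breaks by
  feature index then threshold). The same code serves AdaBoost's weighted
  stumps. Leaf class distributions and leaf-wise acupoint frequencies
  supply the margin scores.
* **Margin learners:** ridge-penalized multinomial linear models via
  `glmnet` (`alpha = 0`, fixed small `lambda`), a max-margin-style convex
  classifier available offline. Acupoint scores are class-probability-
  weighted class-conditional acupoint frequencies from the bootstrap
  sample.

This is a substitution of implementation, not of contract: pool size,
bootstrap-with-replacement training (fraction 1.0 by default — the source
states no sample size), per-learner seeds `f(seed, i)` (order-independent,
reproducible), and the retry-on-missing-class rule all follow the stated
design. Kernel nonlinearity is the main capability lost; on keyword-style
boolean features linear heads plus deep trees cover the useful hypothesis
space well.

## The synthetic world

The real 2835-record dataset is not deposited, so the generator states a
world with the structure the method assumes:

* a latent disease class per record, drawn from a configurable prior
  (the `"paper"` scale uses the published 21 per-disease record counts,
  481 + 75 + ... + 26 = 2835, as the prior and mirrors the
  (31, 11, 4000, 53) schema);
* per-disease keyword templates (8 keywords each) firing with probability
  `keyword_on_prob = 0.9` over a background rate of `0.02` — high-signal
  features over sparse noise, like dictionary hits on real diagnosis text;
* per-disease acupoint templates (6 acupoints, matching the worked plan
  size in the source's sample record) with per-bit flip noise `0.05` —
  doctors mostly, but not always, follow a canonical plan;
* basic info drawn from per-disease normal distributions; the default means
  are shared across diseases (demographics are weakly predictive in
  practice), so the disease signal lives in the keywords;
* a deterministic disease -> (ICD-10, TCM code) assignment. The source
  never defines the cardinality of the TCM code space nor the 21-disease
  to 31-label mapping; the package defaults to 10 codes (`"paper"` scale)
  assigned cyclically, and an injective identity mapping of diseases into
  the first 21 ICD-10 columns.

What a green test establishes: the pipeline's mechanics — scoring, ranking,
selection, weight fitting, protocol — are correct on data with the assumed
structure, including exact recovery in the zero-noise limit. What it does
not establish: performance on real clinical text (no Chinese NLP, no
correlated comorbidities, no annotator disagreement), and in particular the
published headline accuracies, which are not reproducible without the
original records.

## Numerical choices

* All ties anywhere (class scores, votes, ranks, argmax) resolve to the
  lowest index, so every path is deterministic given seeds.
* Majority votes on acupoints and the boosting threshold treat the exact
  boundary (`y' = 0.5`, half-half vote splits) as positive.
* Solver stopping: objective improvement per sweep `< 1e-8` or 200 sweeps.
* The Hamming loss keeps the literal truth-set-size normalization (which
  can exceed 1 for oversized predictions); the conventional label-universe
  normalization is available (`normalize = "universe"`). Empty truth sets
  are rejected as undefined rather than silently skipped.
* Cross-validation spreads are standard deviations across all
  `folds x repeats` runs by default; `aggregate = "repeats"` switches to
  the spread of repeat-level fold averages (the source wording admits both).
* Report cells round half-away-from-zero to one decimal.
* `round()` (banker's rounding) decides the selection size from `b`;
  the floor of one learner always applies.

## Known limitations

* No kernelized margin learners; `glmnet` heads are linear in the features.
* The multinomial margin learner is impractical at the full 4000-keyword
  schema with a 1000-learner pool; full-scale runs should lean on the tree
  half of the pool or reduced dictionaries. Tests and examples run the
  small scale.
* The generator draws class sizes multinomially from the prior; realized
  per-disease counts wobble around the published sizes rather than equal
  them exactly.
* The comparison methods of the original evaluation (multiview KNN, CNN)
  are out of scope; their published per-disease means ship as a data table
  (`icd10_benchmark()`) solely so report-level operations such as
  `count_best_method()` can be exercised against real numbers.
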