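---
title: "Hybrid grey-wolf/annealing gene selection: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid grey-wolf/annealing gene selection: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gwolfsel)
```

## The problem

Case-control transcriptomic studies measure on the order of $10^4$ genes on
at most a few hundred samples. Predictive gene signatures must therefore be
found in a combinatorial space ($2^{AF}$ subsets of the $AF$ measured
features) where exhaustive search is impossible and univariate screening
misses interactions. `gwolfsel` implements a *wrapper* selector: candidate
subsets are encoded as binary masks and scored by the held-out performance of
a classifier ensemble, and the mask space is searched by a binary grey wolf
optimizer (BGWO) hybridized with simulated annealing (SA). Around that core
the package provides the standard upstream stages — merging studies with
empirical-Bayes batch adjustment, differential expression screening — and a
synthetic data generator so the whole system can be exercised and tested
without any external downloads.

## The selection objective

For a mask selecting $NF$ of $AF$ genes, the data are split 60/20/20
(stratified by class) into training, validation and test partitions. The
training partition is SMOTE-balanced (synthetic minority samples interpolated
between minority nearest neighbors), four base classifiers are fitted on the
selected columns — gradient boosted trees, a linear-kernel SVM, a random
forest and a CART tree — and each classifier $i$ receives a weight from its
validation metrics,

$$fw_i = \frac{Ac_i\,Pr_i\,Re_i\,F1_i\,F2_i}{\sum_k Ac_k\,Pr_k\,Re_k\,F1_k\,F2_k},$$

used in a weighted hard vote. With $Avg$ the mean of the ensemble's
validation accuracy, precision, recall, F1 and F2, the default fitness is the
minimized form

$$Fit = \varphi\,(1 - Avg) + (1-\varphi)\,\frac{NF}{AF}, \qquad \varphi = 0.8 .$$

**Why the complement.** The published additive form
$\varphi\,Avg + (1-\varphi)\,NF/AF$, read as a quantity to maximize, rewards
*larger* feature sets, which contradicts both the purpose of the penalty term
and reported fitness values near 0.05 for subsets using ~13% of the features.
The minimized complement reproduces those operating points exactly
(`fitness_value(0.978, 1404, 10629)` gives 0.0440) and is the default;
`form = "literal"` evaluates the additive form verbatim for comparison.

Other objective conventions:

* **Degenerate denominators.** A metric whose denominator is zero (e.g.
  precision with no positive calls) is reported as 0 and flagged, so the
  weight products stay finite instead of propagating `NaN`.
* **Voting ties** go to the cancer class — the conservative direction for a
  screening objective; configurable.
* **Empty mask** short-circuits to the sentinel worst fitness 1 without
  training.
* **Caching.** Fitness values are cached by mask; the metaheuristics revisit
  solutions constantly (annealing rotations especially), and identical
  `(mask, seed, data)` always returns the identical `FitnessValue`.
* **SMOTE granularity.** The training partition is balanced once per split in
  the full feature space and masks then select columns of the balanced
  matrix. Balancing inside every fitness call in the selected subspace would
  make each mask's training set geometrically different and fitness values
  incomparable across masks, besides multiplying cost.
* **Base-learner settings** are fixed and deliberately light (8 boosting
  rounds of depth 2, 25 forest trees, linear SVM, CART with no
  cross-validation pruning), sized for training partitions of one-to-few
  hundred samples where the wrapper evaluates thousands of masks per run.
  The held-out *evaluation* panel (below) uses conventionally sized models
  instead; the wrapper only needs a consistent, cheap comparative signal.

## The search

**BGWO.** Wolves are binary masks. Per iteration the exploration factor
decays linearly, $a = 2 - 2t/t_{max}$; each wolf moves against the three
best masks (alpha, beta, delta): per dimension, coefficient draws
$A = 2ar_1 - a$, $C = 2r_2$ give a distance $D = |C X_{leader} - X_{wolf}|$,
squashed through a steep sigmoid $s = \sigma(10(AD - 0.5))$ and binarized
against a shared uniform draw; the leader's bit OR the binary step gives one
candidate per leader, and a uniform three-way crossover picks the new bit.
Draw granularity (fresh $r_1, r_2$ per dimension and leader; one $r_3$ and
one $r_4$ per dimension) is documented in `wolf_update_draws()` and pinned by
a dual-implementation test that replays the equations scalar-by-scalar.

Leaders are re-ranked every iteration (ties: fewer selected features, then
wolf index); the best-so-far mask is recorded separately, so the reported
trace is non-increasing by construction.

Note a structural property of the published update rule: the combination
step `leader OR bstep` can add features relative to a leader but never
remove them, so parsimony enters only through leader selection, not through
the move itself.

**SA refinement.** At the end of every BGWO iteration the alpha mask seeds an
annealing walk: a roulette wheel picks one of five neighborhood operators —
swap, insertion, inversion, rotate-left, rotate-right — and worse proposals
are accepted with the Boltzmann probability $e^{-\Delta f/T}$. All five
operators permute bits, hence conserve the number of selected features; the
walk explores *arrangements* at fixed subset size. A bit-flip operator that
does change subset size exists behind a non-default flag rather than being
silently added to the published operator set. The schedule (start 0.1,
geometric factor 0.9, floor $10^{-3}$, five proposals per level) is not
specified by any source; the start temperature is set at the scale of
early-run fitness differences (~0.01–0.1) so worse moves are occasionally
accepted early and effectively never near the floor. The refined mask
replaces alpha only when not worse, which preserves the monotone trace.

**Restarts.** The study protocol runs the selector ten times
(`select_restarts()`, seeds 1..10 by default) and keeps the best-fitness run.

## Held-out evaluation

`evaluate_feature_set()` retrains a six-member panel — gradient boosted
trees, CART, random forest, SVM (RBF, probability outputs), k-nearest
neighbors, and a single-hidden-layer neural network — on the union of the
SMOTE-balanced training and the validation partitions, restricted to the
selected genes, and reports F1, PR-AUC, ROC-AUC, MCC and balanced accuracy
per classifier and their mean on the untouched test partition. Training on
train∪val (rather than train only) uses all non-test data once selection is
frozen; the choice is flagged here because the alternative is defensible too.
The test partition never enters any fitness evaluation — the oracle records
the sample ids it sees, and the suite asserts the test ids are absent.

## Upstream stages

* **Merging.** Studies are merged on the *intersection* of their gene sets
  (a union would create missing values the pipeline cannot represent), then
  adjusted with parametric empirical-Bayes ComBat, including the class label
  as a covariate by default so biology is not absorbed into batch estimates
  (disable with `use_labels = FALSE` if labels are confounded with batch).
  The PCA diagnostic quantifies success as the point-biserial correlation
  between PC1 scores and the batch indicator. Adjustment is *nearly*
  idempotent: EB shrinkage leaves per-gene residual batch effects of order
  $10^{-3}$ on the synthetic fixture, so a second pass moves values by about
  two orders of magnitude less than the first rather than by zero.
* **Differential expression.** Per-gene log2 fold change (cancer minus
  normal means) with a Welch t-test by default or limma's moderated t as an
  option, Benjamini–Hochberg adjustment, and the joint DEG rule
  $|logFC| > 2$ and adjusted $p < 0.05$. The threshold is interpreted on the
  absolute value (both up- and down-regulation), and the adjusted — not raw —
  p-value enters the rule.
* **"Unexpressed" filtering.** RMA-scale data have no literal zeros, so the
  filter offers two explicit operational definitions: zero-variance rows
  (default) or all-values-below-a-threshold; both log what they removed.
* **Baselines.** A generational GA (tournament size 3, uniform crossover at
  0.5, bit-flip mutation at $1/AF$ — standard defaults, none prescribed by
  any source), Monte Carlo feature scoring (random subsets scored by
  cross-validated random-forest F1; each member feature credited with the
  subset F1 weighted by its within-subset impurity importance — one concrete
  realization of "presence in high-performing subsets") followed by
  incremental prefix search, and an L1-regularized logistic wrapper.

## The synthetic generator

`generate_dataset()` emulates post-RMA two-class data: per-gene Gaussian
noise (sd 0.5) around a baseline of 7 log2 units, a planted set of
informative genes shifted by 2.5 log2 units in the cancer class with random
sign, and 4:1 cancer:normal imbalance — magnitudes chosen to match what
RMA-processed case-control breast cohorts actually look like (strong DEGs at
$|logFC|$ 2–3, per-gene sds a few tenths). `generate_batched_pair()` adds
per-gene additive shifts (sd 1.0) and optional noise-scale factors to a
second batch over identical biology, the fixture for the merging stage.

What the generator deliberately does **not** emulate: gene-gene correlation
structure, probe-level artifacts, count-based noise, or label noise. Tests
passing on this generator therefore demonstrate that the machinery is
correct and the pipeline has power under clean Gaussian signal — not that
the selector will match its reported behavior on real microarray cohorts.

One consequence matters for interpreting end-to-end checks: with planted
effects of 5 noise-sd, a *single* informative gene supports near-perfect
classification, so ensemble validation metrics saturate for almost every
mask and the fitness surface carries almost no gradient toward the planted
set beyond the feature-count penalty. Combined with the OR-form update (which
cannot drop features) and count-conserving annealing operators, the selected
mask's *enrichment* for planted genes stays near chance even while held-out
F1 is essentially 1 — the honest outcome of running the published update
rules under these study conditions, reported as such by the acceptance
checks rather than patched over.

## Problem sizes used by the test suite

Unit tests run on instances of 20–300 genes and 40–100 samples. The
end-to-end checks use the scaled-down study instance — 160 samples, 500
genes, 30 planted, 4:1 imbalance, 10 wolves, 30 iterations, default
annealing schedule, three seeds — and the acceptance script repeats one such
run plus the batch, DGE and mechanics checks. These sizes were chosen so a
full verification pass completes on a single CPU in well under an hour while
still exercising every stage at realistic ratios of samples to features.

## Known limitations

* Fitness noise: with 20% validation fractions of small cohorts, single
  validation samples move metrics by several percent; comparisons among
  near-equal masks are dominated by this noise. Larger validation fractions
  or repeated splits would stabilize rank order at added cost.
* The BGWO update as published cannot reduce the selected-feature count of
  the leader set (see above); subset shrinkage relies on initialization
  diversity and leader selection.
* Parametric EB assumes roughly Gaussian per-gene errors; heavy-tailed
  contamination would call for the non-parametric variant, which is out of
  scope.
* The probe-collapse step supports many-to-one mean aggregation only
  (no max/median variants).
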