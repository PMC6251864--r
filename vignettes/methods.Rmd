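---
title: "Methods: how m5cpred builds, calibrates and evaluates its predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how m5cpred builds, calibrates and evaluates its predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical and numerical choices behind
`m5cpred`: what is computed, with which defaults, and why. Code chunks are
illustrative and not evaluated at build time; the README shows a fully
worked run with its actual output.

## Problem setting

Given a transcript sequence, every cytosine is a candidate m5C site. The
predictor's job is to rank candidates by the probability that they are
modified, using only the local sequence context, and to turn that ranking
into calls at a controlled false positive rate (FPR). Because true sites
are rare (typically well under 5% of cytosines), both the training
protocol and the evaluation protocol must treat the class imbalance
explicitly rather than wish it away.

## Sequence windows and encodings

A candidate site is represented by the window of `2w + 1` bases centred on
it, with `w = 10` (a 21-nt window) as the default. This width is a
conventional compromise: wide enough to cover the local motif context that
sequence-based m5C predictors rely on, small enough that edge effects and
feature dimensionality stay modest. Windows that overrun a transcript end
are padded with `N`, and `extract_window()` records how many positions were
padded. The centre base must be `C`; anything else is treated as a corrupt
site table and raises an error rather than silently producing a
meaningless feature vector.

Two encodings are provided, both yielding 4 features per position (84 for
the default window):

* **One-hot** (`scheme = "one_hot"`, the default): `A = (1,0,0,0)`,
  `G = (0,1,0,0)`, `C = (0,0,1,0)`, `T = (0,0,0,1)`, `N = (0,0,0,0)`.
  This is the representation the production forest is trained on.
* **Physicochemical** (`scheme = "feng"`): each base maps to a triple of
  binary chemical-property indicators — purine vs pyrimidine, amino vs
  keto, weak vs strong hydrogen bonding — `A = (1,1,1)`, `G = (1,0,0)`,
  `C = (0,1,0)`, `T = (0,0,1)` — plus a fourth coordinate, the accumulated
  frequency of that base among positions 1..i of the window. `N` positions
  contribute zeros and are excluded from the frequency denominators, so
  padding does not distort composition statistics.

Feature names are position-major (`p-10.A` … `p+10.T`), so coefficients
and importances are directly interpretable.

## Dataset construction

`build_comprehensive_dataset()` and `build_tissue_datasets()` implement
the splitting protocol:

1. **Test split.** One quarter of the positive sites (`test_fraction =
   0.25`, `round(0.25 n)`) is held out, stratified nowhere — the split is
   a simple random draw under a fixed seed.
2. **Training negatives.** Negatives for training are drawn at a 1:30
   positive:negative ratio (`ratio = 30`), i.e. `min(30 * n_pos,
   available)` candidate C's from the training-side transcripts, excluding
   every known positive. The cap matters: a forest trained on the raw
   (often 1:100+) imbalance degenerates toward the majority class, while
   1:30 retains enough imbalance for the score distribution to resemble
   deployment.
3. **Test negatives.** The test set keeps **all** candidate C's on the
   test-positive transcripts (minus any that were used for training), so
   measured specificity and FPR reflect what a user scanning whole
   transcripts would see. This "1:all" test convention is the single most
   important protocol choice; subsampled test negatives would flatter
   every model.
4. **Cross-tissue exclusion.** In the per-tissue datasets, each tissue's
   test set additionally drops any site that appears in *another* tissue's
   training set. Without this, the inter-tissue entries of the benchmark
   matrix would partially test on training data.
5. **Comprehensive set.** Pooling all tissues' sites de-duplicates on
   (transcript, position) so a site observed in several tissues is used
   once.

All of this is pure in (inputs, seed): the same arguments always
reproduce the same tables bit-for-bit.

## Models

`train_predictor()` fits one of four learners on the encoded windows:

* **Random forest** (production model): a 300-tree *probability forest*
  via `ranger`. Each tree contributes its terminal-node class proportions
  rather than a hard vote, so the ensemble score is an average of
  continuous leaf probabilities. This choice is deliberate: vote-fraction
  scores from a classification forest are quantised to multiples of
  1/n_tree, with heavy ties in the low-score region, which makes accurate
  FPR calibration at the 1% level impossible on a 2000-negative batch.
  Probability forests give a nearly continuous score at identical
  training cost. 300 trees is the default; growing the forest further
  does not measurably change held-out AUC (there is a regression test for
  this).
* **Logistic regression** (`stats::glm`). One-hot columns sum to 1 within
  each position, so the design matrix is rank-deficient by construction;
  the fit is still well-defined on the prediction side and the
  rank-deficiency warnings are suppressed.
* **Naive Bayes** (`e1071::naiveBayes`, Laplace 0).
* **Decision tree** (`rpart`; `min_split = 35`, `complexity = 1e-5`,
  `max_depth = 30`) — a deep, lightly-pruned tree that serves as the
  "single tree vs forest" ablation.

All learners emit an estimated positive-class probability in [0, 1], and
all training is reproducible under a fixed seed (single-threaded ranger,
seeded base RNG restored afterwards via an internal `local_seed()`).

## Stringency thresholds

`calibrate_thresholds()` converts the continuous score into three call
levels by choosing cutoffs on a batch of *held-out negatives*:

* `high` — nominal FPR 1%
* `medium` — nominal FPR 5%
* `low` — nominal FPR 10%

Two conventions are implemented:

* `"nearest"` (default): the cutoff whose *attained* FPR on the
  calibration batch is closest to the nominal level, breaking ties toward
  the stricter cutoff. Because scores are discrete at some resolution,
  the exactly-nominal FPR is generally not attainable; nearest-FPR makes
  the attained rate an unbiased estimate of the nominal one, which is the
  property a user of "5% stringency" actually wants.
* `"conservative"`: the classical order-statistic rule (the
  `ceil((1 - alpha) n)`-th smallest negative score), which guarantees
  attained FPR ≤ nominal but systematically undershoots on granular
  scores.

Calibrated levels are forced monotone (high ≥ medium ≥ low cutoff), the
calibration size is recorded, and a warning is raised when the batch is
too small to resolve the strictest level (n < 1/min(FPR)). Calls use a
strict `score > cutoff` comparison so that, in particular, a degenerate
all-equal score batch yields zero calls rather than 100% calls.

With the defaults (2000 calibration negatives), the medium threshold's
attained FPR on fresh negatives falls within the 99% binomial interval of
5% — this is checked end-to-end in the acceptance tests and measured by
`scripts/acceptance.R`.

## Evaluation

`roc_curve()` and `auc()` are written from first principles rather than
delegating, because the package's guarantees are about these exact
definitions:

* The ROC curve steps through score thresholds in decreasing order,
  grouping tied scores into single steps (tie-grouping is what makes the
  curve well-defined for granular scores), with fixed endpoints (0,0) and
  (1,1). The area is the trapezoidal rule over that curve.
* `auc()` computes the same quantity independently via midranks
  (the Mann–Whitney U statistic), so ties contribute 1/2. The two
  implementations agree to 1e-12 on randomized instances, and both agree
  with an external ROC package used purely as a test oracle.

`cross_tissue_benchmark()` evaluates every (predictor, test set) pair and
returns a tidy table plus an AUC matrix; `summary()` reports diagonal
(intra-tissue) vs off-diagonal (inter-tissue) means. On data with
tissue-specific signal the diagonal mean should exceed the off-diagonal
mean — this is the package's operational definition of "tissue-aware".

## The synthetic benchmark

`synthetic_spec()` / `simulate_m5c()` generate a self-contained benchmark:
i.i.d. background transcripts from a fixed base composition, with each
tissue's 9-nt consensus motif written over the background at
Poisson-sampled, non-overlapping loci; the motif's anchor C becomes a
positive site and every remaining C an implicit negative. Implantation
*overwrites* sequence rather than rejection-sampling natural matches,
which keeps the positive count exact and the generator simple — the cost
is that background occurrences of a motif remain labelled negative, which
acts as a small, realistic label-noise floor. An explicit `label_noise`
parameter can flip labels on top of that.

The default conditions — 60 transcripts of 800–1200 nt, composition
A/C/G/T = 0.30/0.22/0.22/0.26, three tissues with mutually distinct
motifs, 2 expected positives per transcript per tissue — are fixed study
conditions chosen so that (a) there are dozens of negative candidates per
positive, so the 1:30 ratio machinery actually binds, (b) thousands of
never-touched negatives remain for threshold calibration, and (c) the
per-tissue motifs are distinct enough that intra-tissue transfer
measurably beats inter-tissue transfer. They are not tuned knobs, and the
package's tests treat them as given.

**Scope and limits.** The generator produces an idealised planted-motif
world: real m5C signal is weaker, context-dependent and partially shared
across tissues, so absolute AUCs near 1.0 on synthetic data say nothing
about absolute performance on biological data. What the synthetic
benchmark *does* validate is the machinery: leak-free splits, calibration
accuracy, ranking correctness, reproducibility, and the qualitative
intra- vs inter-tissue ordering.

## Reproducibility

Every stochastic step takes an explicit seed and restores the caller's
RNG state. Model bundles (`save_predictor()` / `load_predictor()`) store
the full predictor in an RDS alongside a human-readable JSON manifest with
a checksum; loading verifies the format version and checksum, and a loaded
predictor reproduces in-memory scores and thresholds bit-for-bit.

## Limitations

* Only sequence context is used; no secondary structure, conservation or
  expression features.
* The feature window is fixed-width; very short transcripts are handled
  by `N`-padding rather than variable-length modelling.
* Threshold calibration assumes the calibration negatives are
  exchangeable with deployment negatives; a shifted negative distribution
  (different composition, different species) will shift the attained FPR.
* The synthetic generator is a verification instrument, not a biological
  simulator (see above).
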