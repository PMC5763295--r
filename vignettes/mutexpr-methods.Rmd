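---
title: "Classifying genome aberrations by their transcriptional effects"
author: "mutexpr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying genome aberrations by their transcriptional effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutexpr)
```

## The problem and the model

Tumors accumulate many genomic aberrations — point mutations, small
insertions and deletions, and large copy-number changes — but only a few of
them drive tumor biology, and different driver genes can converge on the
same signaling cascades. `mutexpr` implements a pan-cancer analysis built
on one modelling idea: *if aberrations in two genes leave similar
footprints on the transcriptome, the genes likely act on similar downstream
biology* — and may respond to the same therapies. The package operates on
tumors that carry an aberration in exactly one of a set of cancer genes
(mutual exclusivity), trains a probabilistic classifier to predict the
mutated gene from expression, and reads off gene–gene similarity from the
correlation of the predicted class probabilities.

The pipeline has four statistical stages:

1. **Aberration calling.** Annotated somatic variants are filtered: a call
   survives iff it passed the caller's quality control, its ExAC population
   frequency is missing or ≤ 0.01, its predicted impact is not
   LOW/MODIFIER, and it is predicted deleterious by SIFT, damaging by
   PolyPhen-2, or carries no prediction from either tool. Thresholded
   copy-number values contribute an aberration only at ±2 (homozygous
   deletion, high-level amplification). Variants and copy-number events are
   merged to a Boolean gene × sample matrix over a cancer-gene panel,
   restricted to samples with all three data types.
2. **Expression preparation.** TPM values from re-sequenced tumors are
   averaged, transformed as log2(x + 1), and — whenever the analysis spans
   several cancer types — adjusted for cancer type with a parametric
   empirical-Bayes location–scale model (below).
3. **Cohort construction and classification.** A three-step pass builds the
   mutually exclusive training set (genes aberrant in ≥ *m* samples; keep
   samples aberrant in exactly one such gene; keep genes still at ≥ *m*).
   A random forest predicts the class label under stratified 5-fold
   cross-validation. Because class sizes are unequal, every class is first
   down-sampled to the minimum class size, and the whole procedure is
   repeated (default 10×) with different subsampling seeds; metrics are
   averaged over the repeats. Performance is summarised as one-vs-rest
   AUROC per gene (Mann–Whitney formulation, half credit for ties) and
   arg-max multiclass accuracy, against chance levels of 0.5 and 1/K.
4. **Similarity and projection.** For every pair of training genes the
   Spearman correlation between their probability columns is computed per
   repeat and averaged: a high value means the classifier confuses the two
   classes in the same tumors, i.e. their downstream effects are similar.
   For rarely mutated genes (the test set, restricted to genes with
   "Supported" drug–gene evidence and ≥ 5 aberrant samples), a model
   trained on the full training set produces probabilities that are
   correlated with the rare-gene indicator, relating rare aberrations to
   common classes.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `min_train_count` | 10 (single type), 50 (pan-cancer) | minimum aberrant samples per training gene |
| `min_test_count` | 5 | minimum aberrant samples per test gene |
| `maf_max` | 0.01 | ExAC frequency ceiling for somatic calls |
| `k_folds` | 5 | cross-validation folds (stratified by class) |
| `n_repeats` | 10 | balanced-subsampling repeats |
| `num_trees` | 500 | forest size; `mtry` defaults to √p |
| `eligibility` | ≥ 3 classes at `min_train_count` | per-type analysis gate |

All thresholds are arguments, never constants; `run_pipeline()` wires them
from a single declarative (YAML-able) configuration.

## The empirical-Bayes batch adjustment

Tissue of origin dominates tumor expression, so pan-cancer analyses adjust
for cancer type as a batch effect. Per gene, the matrix is standardised
against the batch-size-weighted grand mean and pooled variance; per batch,
gene-wise location and scale parameters are shrunk toward batch-level
priors (normal on locations, inverse-gamma on scales, moment-matched
hyperparameters) by iterative conditional estimation to a relative
tolerance of 1e-4 (cap 100 iterations); the data are rescaled to the
pooled moments. No biological covariates are protected. Two deliberate
choices:

* **Exact pooled-mean restoration.** After adjustment each gene is
  re-centred so its pooled mean is exactly preserved. EB shrinkage
  otherwise perturbs pooled means by a small batch-imbalance term; the
  re-centring makes the "adjustment changes within-batch structure, not
  gene-level location" contract exact. The unit tests verify agreement
  with the reference implementation in the `sva` package up to this
  re-centring (max difference ~1e-6 on shared test data).
* **Degenerate inputs.** Zero-variance genes pass through unadjusted (with
  a message); a single-batch matrix is returned unchanged; a batch with
  one sample is an error naming the batch, since its scale cannot be
  estimated.

A follow-up confounding check is part of the pipeline: cancer type remains
predictable from adjusted expression (a subtle footprint survives any
location–scale adjustment), and mutation status is partially predictable
from cancer type alone, so pan-cancer similarity values should be read
with that caveat.

## The synthetic-cohort generator

Real pan-cancer data cannot ship with a package, so `simulate_cohort()`
generates full cohorts with known ground truth, emitting the same six
files the pipeline reads. The generative model, on the log2 scale:

> value(g, s) = baseline(g) + shift(type(s), g) + signature(driver(s), g) + ε

with `baseline ~ N(4, 1.5)`, per-type shifts `N(0, tissue_shift_sd²)`,
noise `N(0, noise_sd²)`, and export to the TPM scale via `2^x − 1`
(floored at 0) so the pipeline's own `log2(x + 1)` recovers the latent
scale. Driver signatures are gene-length vectors with *exact* pairwise
sample correlations: a centred orthonormalised Gaussian basis is combined
through the symmetric square root of the target correlation matrix, which
also handles rank-deficient targets (correlation ±1). Vectors are
unit-normalised and scaled by `effect_size · √G`, making `effect_size` the
root-mean-square per-gene effect in log2 units. Non-positive-semi-definite
overlap targets are rejected.

Aberrations are emitted the way the pipeline expects to find them: each
driver event becomes, by coin flip, either a passing deleterious variant
record or a ±2 copy-number call, exercising the merge path. Passenger
variant records are engineered so that each filter rule removes some of
them (non-PASS; frequency > 0.01; LOW/MODIFIER impact; tolerated+benign),
and filter-surviving passengers are placed outside the gene panel so that
strict mutual exclusivity holds in the emitted files, not only in the
ground truth. A configurable fraction of samples is emitted twice
(re-sequenced tumors, fresh noise).

Defaults emulate a mid-sized study that runs in seconds: 5 drivers ×
50 samples, 500 expression genes containing a 325-gene panel, 3 cancer
types, `effect_size = 1`, `tissue_shift_sd = 1`, `noise_sd = 1`. These
choices make tissue the dominant variance component before adjustment
(as in real tumor compendia) while leaving driver signatures clearly
recoverable after it.

**What the generator does not emulate:** mutational sequence context,
subclonality, copy-number segment structure, correlated gene modules,
count-level noise, or expression-dependent mutation selection. Passing
tests therefore demonstrate that the *procedure* is implemented correctly
and is calibrated on its stated model — not that real tumors satisfy that
model.

## Numerical and design choices

* **Classifier contract.** Any object providing `fit(x, y, seed)` and
  `predict(model, x)` → row-stochastic probability matrix can be plugged
  in. The reference is a seeded, single-threaded probability random forest
  (`ranger`, 500 trees, √p candidate features per split). "Default
  parameters" differ across random-forest implementations; the contract,
  not a particular library's defaults, is what the analysis depends on.
* **Folds are stratified by class.** With 10 samples per class and 5
  folds, unstratified splitting can produce folds missing a class
  entirely.
* **Arg-max ties** break toward the first gene in alphabetical order —
  deterministic and documented; with continuous probabilities ties are
  rare.
* **Repeat averaging.** Metrics and pair correlations are computed within
  each balanced-subsampling repeat and then averaged (pooling across
  repeats would re-count the same samples); for test-set projection the
  per-sample probabilities are averaged across the repeat models instead,
  since test samples are fixed.
* **Similarity p-values** use the t-approximation on the repeat-averaged
  rho with the per-repeat sample count, Bonferroni-corrected over the
  pairs tested in that analysis scope (e.g. C(5,2) = 10), not over the
  panel-wide 52,650 pairs used for single-gene expression tests. A seeded
  permutation mode is available for `spearman_cor()`.
* **Test-set exclusivity.** A test sample must be aberrant in exactly one
  candidate test gene, and training assignment takes precedence; both
  rules make test labels well-defined where the protocol would otherwise
  be ambiguous. Samples excluded for multi-gene conflicts are logged.
* **Single-pass cohort construction.** Samples discarded for a conflict
  with a gene that is itself later discarded are *not* re-admitted; the
  construction follows the three steps literally rather than iterating to
  a fixpoint.
* **Welch by default.** Single-gene group comparisons default to the
  unequal-variance t-test with Satterthwaite degrees of freedom
  (`var_equal = TRUE` switches to the pooled test).
* **Association of rare genes** is defined as the Spearman correlation,
  across test samples, between the rare-gene indicator and a training
  class's predicted probability — one number per (test, training) pair.
  Other operationalisations exist; this one is symmetric-free,
  scale-free, and testable. It requires at least two test genes (with one
  test gene the indicator is constant and the association is undefined,
  which the code flags).

## Calibration notes and known limitations

* At the default validation scale (50 positives vs 200 negatives) the
  *null* sampling standard deviation of one-vs-rest AUROC is
  √((n₁+n₂+1)/(12 n₁ n₂)) ≈ 0.046, so individual per-gene null AUROCs
  regularly land outside 0.5 ± 0.06 for purely stochastic reasons — for
  any classifier, however well calibrated. Multiclass accuracy, which
  pools all 250 samples, is much tighter around 1/K. Calibration checks
  at this scale should therefore lean on accuracy and on the *mean*
  per-gene AUROC rather than on per-gene extremes.
* With equal class sizes, balanced subsampling is the identity, and
  repeats only average fold-assignment and forest randomness. The
  planted-pair recovery study (20 generator seeds) therefore uses 3
  repeats; signal and null calibration use the full 10.
* Problem sizes in the tests (tens of genes, tens of samples per class for
  unit tests; the 5 × 50 × 500 default for validation) were chosen so the
  whole suite runs in a few minutes on one core; they are stated here as
  the package's validation conditions.
* Bonferroni over all panel pairs is conservative for the single-gene
  tests; no FDR alternative is provided because the analysis uses the
  corrected values only as a screen.
* Epigenomic aberrations (methylation, miRNA, fusions) are out of scope;
  all mutations within a gene are treated as equivalent.

## Reproducibility

Every stochastic step — simulation, subsampling, fold assignment, forest
growth, permutation tests — flows from explicit integer seeds, and the
pipeline writes tidy TSVs that are byte-identical across runs with the
same configuration and seed. `scripts/acceptance.R` regenerates the
package's headline numbers from scratch; see the README for how to run it.
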