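---
title: "Classifying cell-cycle states with likelihood rejection: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cell-cycle states with likelihood rejection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model and its
assumptions, the parameters that matter, what the synthetic-data generator
does and does not emulate, the numerical choices, and the design decisions
taken where the design was genuinely open. No empirical number is quoted
here that the test suite or `scripts/acceptance.R` does not itself compute.

## The classifier

`ccann` assigns each cell one of seven transcriptional cell-cycle states —
Neural G0 (a quiescent-like state), G1, Late G1, S, S/G2, G2/M, and
M/Early G1 — from the expression of a fixed gene panel. The model is a
fully connected network: a dense input layer over the panel genes, two ReLU
hidden layers of 600 and 200 neurons, and a softmax output with one neuron
per state. Two dropout layers (rate 0.5) sit after each hidden layer and
regularize training; dropout is inverted (activations scaled by `1/(1-p)`
at train time), so inference needs no rescaling and is fully deterministic.

Training minimizes categorical cross-entropy with minibatch stochastic
gradient descent. The schedule is five consecutive rounds of ten epochs;
each round redraws a random 80/20 partition and the 20% is only used to
record monitoring loss and accuracy, while weights carry over across
rounds. Because every round redraws the split, late-round "holdout"
accuracy is an optimistic monitor, not an unbiased generalization estimate
— generalization should be measured on cells never passed to
`train_classifier()`. Class proportions are left as they come: rebalancing
the training labels is deliberately not offered, since weighting was found
to hurt this kind of classifier, and the F1 metric used throughout already
accounts for imbalance.

The decision rule converts softmax likelihoods to labels: the argmax state
is emitted iff its likelihood reaches the threshold `t` (default 0.5,
adjustable in [0, 1]); otherwise the cell is labeled `"Unknown"`. The
non-Unknown cell set is monotone non-increasing in `t` — an exact
set-inclusion property that the tests check — and `t = 0` disables
rejection entirely. Merging Neural G0, G1, and Late G1 into a single
`G0/G1` label (`collapse_g0g1()`) is offered for tissues where the
quiescent-adjacent states are not separable; it is idempotent and leaves
all other labels, including `"Unknown"`, untouched.

### Hyperparameters and their defaults

| parameter | default | why |
|---|---|---|
| `hidden1`, `hidden2` | 600, 200 | funnel from the panel size toward 7 states; the grid search module reproduces the selection experiment |
| `dropout_rate` | 0.5 | strong regularization for a wide network on small panels |
| `epochs_per_round`, `rounds` | 10, 5 | the canonical training schedule |
| `holdout_fraction` | 0.2 | monitoring split per round |
| `learning_rate`, `momentum`, `batch_size` | 0.01, 0.9, 32 | conventional SGD settings for a small dense net; the method's guarantees are property-based, not tied to exact weights |
| `threshold` | 0.5 | at least 50% certainty before a state is emitted |

Weight initialization is He-style (uniform on ±sqrt(6/fan-in)) from a
stream seeded by `model_config(seed = )`; the same seed drives the round
splits, the per-epoch shuffling, and the dropout masks, so two trainings
with identical inputs and seed are bit-identical. Ties in the argmax are
broken in favor of the earlier state in the vocabulary order, with a
message counting the ties.

The hidden-layer grid search evaluates widths 200–700 × 100–400 in steps
of 100, restricted to the funnel `hidden1 > hidden2` — exactly 18
combinations — ranking by held-out macro F1 and then by AMI on any
supplied evaluation sets.

## Input processing

Matrices enter genes × cells (the on-disk MTX convention) and are
transposed to cells × features only at alignment; every function states
which orientation it expects. Two normalizations are provided:

* **log-CPM**: `log(1 + 10^4 · count / cell total)` — simple, monotone,
  nonnegative; this is the scale on which marker discovery runs.
* **Pearson residuals**: analytic residuals under a negative-binomial depth
  model, `(x − μ)/sqrt(μ + μ²/θ)` with `μ_ij = depth_j · gene share_i`,
  clipped to ±sqrt(n cells). The per-gene dispersion θ is a
  method-of-moments estimate regularized by a loess fit of log θ against
  log mean expression (median fallback below 20 usable genes). This is a
  contract — "residuals of a regularized NB depth model, clipped" — not a
  re-implementation of any particular package's normalization; the
  classifier is trained and applied under the package's own normalization
  rather than against frozen external weights. Pearson residuals are the
  recommended classification scale: they are centered and
  variance-stabilized, which conditions the SGD problem far better than a
  raw log scale.

All-zero genes map to all-zero rows under both methods; a cell with zero
total count is an error naming the barcode. Duplicate gene identifiers are
summed at load time (counts are preserved under collapsed annotations).

`align_features()` translates identifiers into the panel's system — mouse
symbols through a bundled one-to-one ortholog table, symbol↔Ensembl
through a lookup — dropping ambiguous mappings rather than guessing
(upper-casing symbols across species is deliberately not a fallback).
Panel genes absent from the input become all-zero columns and the missing
fraction is reported; above 20% missing a warning is raised, because
classification error rises steeply with missing panel genes, and complete
non-overlap is a hard error. Alignment is idempotent and commutes with
subsetting cells.

## Marker discovery and the feature panel

`find_state_markers()` performs one-vs-rest differential expression per
state: a two-sided Wilcoxon rank-sum test per gene, vectorized as a
rank-sum z statistic with tie and continuity correction (validated
gene-by-gene against `stats::wilcox.test`), BH adjustment within each
state, and a fold change `log2((mean_in + ε)/(mean_out + ε))` with
`ε = 1e-9` computed on de-logged (`expm1`) means. Only up-regulated genes
passing `log2FC ≥ 0.25` and `p_adj ≤ 0.05` are kept. The classifier panel
is then simply the union of the per-state marker genes
(`feature_space_from_markers()`), mirroring the recipe of training on the
genes up-regulated in cell-cycle states. Fold changes presume a
nonnegative expression scale, which is why discovery always runs on
log-CPM even when classification uses Pearson residuals.

Gene-set overlap uses the upper-tail hypergeometric test, `P(X ≥
overlap)`, with the universe an explicit argument — published overlap
tests often leave the universe implicit, and the p-value is meaningless
without it. Bulk-signature mapping computes the Spearman correlation of
each cell against each bulk replicate over an informative gene set (top
2000 highly variable genes by variance-to-mean ratio that exceed 10 counts
in every bulk replicate, unioned with panel genes present in the bulk), and
a cell is called signature-positive iff it reaches the cutoff (default
0.1) in *all* replicates.

## Permutation feature importance

Baseline likelihoods are computed once; each panel gene's column is then
permuted across cells (a seeded permutation per repeat) and the mean change
in each state's likelihood is recorded — negative means the gene supported
that state. When per-cell labels are available the mean for a state is
taken only over that state's cells, which is the default and recommended
mode. Permuting one feature changes the first-layer pre-activations by a
rank-one update, which the implementation applies exactly; a constant
column is returned by any permutation, so its delta is exactly zero.

One caveat discovered while validating the module: on data a classifier
separates perfectly, the softmax saturates (winning likelihoods pin at 1)
and single-feature permutations barely move any likelihood, so the
importance ranking degenerates into noise. Importance is therefore
informative on data where the classifier operates away from saturation —
in practice, labeled data whose states genuinely overlap, which is what
real cell-cycle data looks like. The package's own validation evaluates
importance on a generator draw with attenuated effect size
(`marker_log2fc = 1`, half the training effect) and 3 permutation repeats,
where the planted markers dominate each state's top-15.

## Removing cell-cycle signal

`module_score()` implements expression-matched scoring: genes are cut into
24 equal-frequency bins by mean expression, each set gene draws 100 control
genes from its own bin (never from the set itself), and the score is the
per-cell mean of the set minus the mean of the pooled controls. Bin count
and control count are the established defaults of this scoring scheme and
are exposed as parameters. `regress_out()` then residualizes every gene on
the chosen module scores by OLS with intercept: residuals are orthogonal to
the covariates and the operation is a projection. The recommended
covariate set for removal is the five proliferative states (Late G1, S,
S/G2, G2/M, M/Early G1). All-zero covariate columns are dropped (they
carry no signal); genuinely collinear covariates are an error suggesting
one be removed. Regression is kept a standalone step on the normalized
matrix rather than folded into normalization: the residual contract is the
same and the two concerns stay decoupled.

Success is judged by co-expression: the variance explained by PC1 of the
marker-gene submatrix, compared against 1000 random gene sets of the same
size drawn from all genes in the matrix (the universe choice is
parameterized; "all genes" is the default). The empirical p-value uses the
add-one convention `(1 + #{random ≥ observed})/(1 + n_random)`, so it is
never exactly zero and its smallest attainable value at 1000 draws is
1/1001. Removal is successful when a set significant before regression
(p ≤ 0.001) becomes non-significant after (p > 0.05).

## Evaluation machinery

**F1** is one-vs-rest per state; `"Unknown"` may appear only in
predictions, where it costs recall but never precision. States absent from
both labelings are not reported rather than scored 0. **Error rate**
excludes rejected cells from numerator and denominator by default — the
rejection option is abstention, not error — with an inclusive mode
available, since the convention is genuinely ambiguous. **AMI** is
mutual information corrected by its expectation under the permutation
model and normalized by the arithmetic mean of the entropies; cells
predicted `"Unknown"` are dropped first (prediction-side only — the
reference is assumed complete). The expected-MI term is computed with
log-gamma sums; the tests check the whole statistic against an independent
brute-force oracle, exhaustively over all pairs of two-valued labelings of
five items and on random 8-item labelings.

Because AMI depends on how many states each labeling uses, raw scores are
hard to compare across classifiers with different vocabularies. The
calibration simulation makes the mapping explicit: reference labels drawn
uniformly over `k_ref` states; a fraction `s` of cells copy their
reference label through the fixed surjection `i → ((i−1) mod k_pred)+1`;
the rest draw uniformly from the predicted vocabulary; AMI is averaged
over 100 replicates of 1000 cells per grid point. Only the curve's shape
is consumed, so the copy-with-probability-`s` scheme is documented rather
than load-bearing. By construction the curve passes through AMI = 1 at
`s = 1` with matched vocabularies and ≈ 0 at `s = 0`.

The threshold sweep applies thresholds 0.0–0.9 (step 0.1) to a 90% random
subsample, recording the percentage of cells surviving and their AMI
against the reference; metrics are left undefined when 20 or fewer cells
survive. The baseline removes the *same number* of cells uniformly at
random: if thresholding helps because it rejects genuinely uncertain
cells, the thresholded AMI rises while the baseline stays flat. The
package's validation realizes "noisy cells" as weak-signal cells — a
generator draw with `marker_log2fc = 0.6` mixed into clean held-out cells —
whose predictions are error-prone and low-confidence, so their mistakes
concentrate below the 0.5 threshold. (An earlier construction, cells with
two states' marker blocks elevated, fails for this purpose: a saturated
classifier still commits confidently to one of the pair. It is retained as
`simulate_boundary_cells()` for doublet-like experiments.)

Missing-gene sensitivity zeroes a random subset of panel columns for all
cells — after normalization and alignment, i.e. at the classifier-input
scale — across fractions, replicates, and thresholds, recording error rate
and percentage predicted.

## The synthetic-data generator

`simulate_dataset()` plants ground truth sufficient to exercise every
module: cells draw states from a simplex of proportions; each state
up-regulates a disjoint block of marker genes by `marker_log2fc` (log2
scale) over a flat baseline; counts are negative-binomial with common
dispersion; and each observed count is independently zeroed with the
dropout probability. A single seed drives state assignment, counts, and
dropout in that fixed order, so identical parameters give bit-identical
matrices.

Defaults are the package's study conditions, fixed once: 7 states with the
cell-cycle vocabulary and uniform proportions; 1000 genes; 15 markers per
state (matching the top-15 importance analyses); `marker_log2fc = 2`;
`baseline_mean = 5`; `dispersion = 2` (variance `μ + μ²/2`, a typical UMI
overdispersion); `dropout_rate = 0.2`. Validation sizes, chosen as the
package's own working scale: 3000 training cells, a held-out 1000-cell
sample, 2000 cells for regression and importance experiments, 10 seeds or
replicates for the contrast experiments.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: gene–gene correlation beyond the planted
block structure, batch effects, doublets, library-size gradients
confounded with state, continuous (rather than discrete) cell-cycle
progression, and overlapping marker programs between adjacent states. The
planted states are linearly separable by construction, which is also why
the trained network saturates on clean draws (see the importance section);
real data sits in the partially-overlapping regime. The bulk-signature
generator resamples a state's cells, scales by a depth factor (default 10)
and applies small log-normal noise — it emulates a deep bulk library of a
sorted subpopulation, not library-preparation biases.

## Numerical choices and degenerate inputs

Softmax subtracts the row maximum before exponentiation; cross-entropy
clips probabilities at 1e-12. Likelihood rows sum to 1 within 1e-6 (tested
per row). Model archives are a single JSON file — a header with format
version, config, vocabulary, panel, marker sets — with weights as
base64-wrapped raw little-endian doubles, because decimal text round-trips
are not bit-exact; loading a truncated or foreign file, or a different
format version, is an explicit error. PCA for the variance-explained
statistic uses an eigendecomposition of the centered cross-product (exact,
and fast for the small gene sets involved); a constant submatrix is an
error rather than a 0/0. Empirical p-values use add-one smoothing. Seeds
are 32-bit integers throughout; helpers derive child seeds for independent
streams.

## Known limitations

The classifier's accuracy guarantees are statements about the generator's
separable regime; on real data the Neural G0 / G1 / Late G1 trio is known
to be hard to separate outside neuroepithelial tissue, which is exactly
what `collapse_g0g1()` is for. Training is single-threaded base-R matrix
arithmetic: ample for panels of a few hundred genes and a few thousand
cells, but not engineered for atlas-scale training (prediction scales
fine). The ortholog and identifier tables are supplied by the user or the
feature space; the package ships no genome-wide annotation. Likelihoods
are raw softmax outputs and are not calibrated probabilities — the
rejection threshold is a working confidence floor, not a guarantee of
error rate.
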