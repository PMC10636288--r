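---
title: "Ant-colony architecture search for expression-based subtype classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ant-colony architecture search for expression-based subtype classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnasearch)
```

## The problem

Transcriptome-defined cancer subtypes — the four colorectal consensus
molecular subtypes (CMS1–CMS4) being the canonical example — are
predicted from bulk expression profiles with tens of thousands of genes
and a few hundred labelled samples per cohort. Feed-forward networks
work well on this task, but their performance hinges on architecture
and regularization choices (depth, layer widths, activations, dropout,
batch normalization, L1/L2 penalties, optimizer, learning rate, epoch
budget) that are usually hand-tuned. `dnasearch` automates that tuning:
it couples a discrete ant-colony search over architecture space with a
boosted-tree surrogate that redistributes search effort toward the
hyperparameters that demonstrably move cross-validated accuracy.

The pipeline is: differential-expression gene filter → architecture
search with cross-validated fitness → final fit and evaluation with
macro per-class metrics.

## The classifier

A candidate ("individual") encodes `[e, τ, α, (ϑ, δ, ρ, ω, γ1, γ2) per
layer]`: epochs, optimizer, learning rate, and per hidden layer the
width, activation, dropout rate, batch-norm flag and penalty
coefficients. The realized network stacks `k` blocks

    dense (W x − θ) → batch norm (optional) → activation → dropout

followed by a dense softmax head, and minimizes the penalized mean
cross-entropy

    L = −(1/n) Σ_i Σ_t y_it log y'_it + Σ_l γ1_l ‖W_l‖₁ + γ2_l ‖W_l‖²_F .

Numerical choices, all documented constants: batch-norm ε = 1e−5 with
biased batch variance; probability clip 1e−12 before the log;
mini-batch size 32 (a trailing singleton batch is dropped when any
layer uses batch norm, which needs m ≥ 2); Glorot-uniform
initialization; inverted dropout (drop probability ρ, survivors scaled
by 1/(1−ρ), inference is the identity) so expected activations are
preserved without test-time rescaling. Optimizers are momentum SGD
(µ = 0.9), RMSProp and Adam at their conventional constants. Training
stops early once validation accuracy has not improved for 50
consecutive epochs (configurable patience), and the weights of the best
validation epoch are kept. Inputs are standardized per gene using the
training-split mean and standard deviation, which are stored in the
model and reapplied at prediction; this stabilizes training across the
very different weight scales the search explores.

Three of these choices resolve ambiguities in the underlying
formulation and are deliberate: the cross-entropy term is minimized as
a negative log-likelihood (the alternative sign would be maximized by
perfect predictions, inconsistent with a loss); the L2 term is the
squared Frobenius norm (consistent with "weight squared" closed-form
shrinkage); penalties are applied per layer with per-layer
coefficients, with the output matrix carrying the last hidden layer's
pair — restricting the penalty to the output layer is reproducible by
zeroing the earlier coefficients.

## The gene filter

For each class, a one-vs-rest comparison computes per gene: the log2
fold change (a difference of means, since inputs are already log2
scale), a Welch two-sample t-test, and a two-sided Wilcoxon rank-sum
test (normal approximation with tie and continuity correction — the
`stats::wilcox.test(exact = FALSE)` convention, which our vectorized
implementation matches to 1e−12). Within each comparison, each test's
p-values are Benjamini–Hochberg adjusted. A gene is selected when
`|log2FC| > 1` **and both** adjusted values fall below 0.05 —
"integrating" the two tests is read as an intersection, the
conservative choice — and the final list is the union across the
one-vs-rest comparisons, kept in matrix order. Degenerate conventions:
a gene constant across all samples has p = 1 under both tests; a
zero-variance gene whose group means still differ has t-test p = 0.
Whether the FDR adjustment should instead pool all comparisons is
genuinely open; within-comparison was chosen because each one-vs-rest
contrast is a self-contained family, and the thresholds are exposed for
sensitivity analysis.

## The search

Architecture space is a layered DAG: one decision slot per
hyperparameter (epochs → optimizer → learning rate → depth → per-layer
slots), one node per candidate value, consecutive slots fully
connected. The depth slot precedes the layer slots, so a walk knows
after which layer to exit; every complete walk decodes to exactly one
valid individual (verified exhaustively on a 64-path pool). An ant
steps from node `r` to value `s` with probability

    P(s) ∝ ξ(r,s)^ᾱ · η(r,s)^β̄

over the feasible candidates. Fitness is the mean stratified k-fold
validation accuracy of the trained network; aborted trainings
(non-finite loss) score 0. Duplicate individuals within the run share
one evaluation through a cache keyed on the encoding — evaluation is
the cost bottleneck and the semantics are unchanged.

**Encoding.** Mixed one-hot/numeric: categorical slots (optimizer,
depth, activation, batch-norm flag) become one-hot blocks, numeric
slots stay raw; unused layer blocks are zero-filled so the vector
length depends only on the pool. `decode(encode(p)) = p` is tested over
1000 random individuals.

**Surrogate.** Each iteration re-fits a least-squares gradient-boosted
regression-tree ensemble on all (encoded individual → fitness) records.
Feature importance is split gain, normalized to sum 1 (`φ`); fit
quality is training R² clipped to [0.01, 1] (`ν`); the heuristic on
every edge into a value becomes `η = ν·φ(column of that value)`,
floored at 1e−6 so no edge dies. xgboost is not available in this
environment, so the ensemble is implemented in the package (depth-3
trees, shrinkage 0.1, no subsampling); one behaviour is essential and
deliberate: **exact split-gain ties are broken at random** (seeded).
The two one-hot columns of a binary slot are perfectly anti-correlated
and induce identical partitions; a deterministic tie-break funnels all
gain into one arbitrary sibling, and through `η` that pushes the
sampler hard toward an arbitrary value — measured on a mock landscape,
that single artifact drove the search below the random-search baseline.

**Pheromone dynamics.** Only the globally best individual deposits:
edges on its path move toward `η·f` by factor φ = 0.1 once per
iteration (a configuration switch offers the conventional plain-`f`
deposit for sensitivity checks). Every traversed edge is locally
evaporated toward ξ0 by factor ψ = 0.1 at the construction step that
uses it, diversifying the colony within an iteration. Both updates are
convex combinations, so pheromone stays positive and bounded between
its old value and the deposit.

**Why ξ0 = 0.01.** The deposit `η·f` is at most an importance mass
(≲ 0.3) times an accuracy (≤ 1). If the initial pheromone sits above
every achievable deposit — e.g. the superficially natural ξ0 = 1 —
"reinforcing" the best path actually lowers its pheromone relative to
untouched edges, and the search performs worse than random sampling (we
measured 6/30 vs the random baseline's ~79% optimum-hit rate on the
64-configuration mock landscape). Ant-colony-system practice likewise
initializes trails well below typical deposits. With ξ0 = 0.01 the
acceptance suite's mock-landscape panel finds the enumerated optimum in
≥ 95/100 seeded runs and dominates a same-budget random search.

Iteration 1 runs with a uniform heuristic (η = 1) because no surrogate
exists yet. Defaults follow the source formulation where it states
them: population 10, 10 iterations (100 fitness evaluations), surrogate
of 1000 trees, ᾱ = β̄ = 1, φ = ψ = 0.1. Tests and the acceptance
script reduce the surrogate to 30 trees purely for runtime; at tens of
records and ~35 encoding columns more trees only sharpen an importance
vector that is already stable.

## Evaluation

Metrics come from the confusion matrix (rows truth, columns
prediction): per class one-vs-rest sensitivity TP/(TP+FN) and
specificity TN/(TN+FP), overall accuracy trace/n, and the macro
accuracy — the mean per-class recall ("average accuracy per class"),
which equals overall accuracy exactly on class-balanced truth.
Multiclass specificity averaging is not defined by the source
formulation; macro averaging over one-vs-rest contrasts was chosen and
is labelled as such. Classes absent from the truth yield NaN rates,
are skipped by macro means, and are counted in `n_undefined`.

`cross_validate()` is leakage-safe: stratified folds, with gene
selection and standardization re-fit inside each training fold. A
deliberate `leak_selection = TRUE` mode performs selection once on the
full data as a negative control — on null data it inflates pooled
accuracy well above chance while the within-fold estimate stays inside
the 3σ band around chance (the classic selection-bias demonstration).
The DEG selector can legitimately select nothing (e.g. under the null);
inside cross-validation it then falls back to the `top_n` smallest
p-value genes so a model can still be fit — real analyses should treat
an empty selection as a warning about the data, not a modelling
instruction. `k = n` is leave-one-out and bypasses stratification;
otherwise a class smaller than `k` is an error suggesting a smaller
`k`.

## The synthetic world

`generate_classification_dataset()` emulates a log2-intensity
microarray matrix: iid Gaussian background `Normal(7, sd)` — log
intensities are approximately Gaussian and 7 is a typical array
mid-range — with disjoint per-class blocks of informative genes whose
mean is shifted by `effect_size` in that class only. Defaults (4
classes, 50/class, 1000 genes, 10 informative/class, effect 2.0,
sd 1.0) are the stated test world for the gene filter; classes are
balanced by default with an imbalance ratio option because real
subtype cohorts are imbalanced. `generate_null_dataset()` draws labels
independently of expression.

What a green test does establish: the filter's operating
characteristics, the learner's capacity, the optimizer's exploitation,
and the leakage guard, all under a world where the signal is exactly
known. What it does not: robustness to batch effects, platform shifts,
gene-gene correlation, count-based noise, or class overlap structure —
none of which the generator simulates. Headline accuracies on real
cohorts are therefore out of reach of this test bed by design, and the
acceptance checks are property-based instead.

## Known limitations

* Fitness uses the early-stopping validation fold itself, so per-fold
  accuracies are mildly optimistic as absolute estimates; they are used
  comparatively, which is what the search needs. Final models should be
  assessed with `cross_validate()` on held-out folds, as the pipeline
  does.
* The surrogate heuristic is direction-agnostic: importance says a
  hyperparameter *matters*, not which value is good. Direction comes
  only from the pheromone deposits.
* Pure-R training is sized for desk-scale problems (hundreds of
  samples, tens to hundreds of filtered genes); cohort-scale searches
  are possible but slow.
* The pheromone graph treats per-layer slots independently;
  conditional pools (e.g. optimizer-specific learning rates) are out of
  scope.
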