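---
title: "Methods: inferring a functional interactome and testing gene set linkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring a functional interactome and testing gene set linkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsla)
```

## The problem

A list of differentially expressed genes (an observed transcriptomic change,
OTC) is usually interpreted by asking which established biological processes
it is *enriched* in. Enrichment fails when the changed genes themselves are
not members of any annotated process, even though they collectively act on
one. Gene set linkage analysis (GSLA) asks the complementary question:
do the changed genes have *dense functional associations* with the genes of
an established process in a reference interactome? Answering it requires
(i) a high-quality functional interactome, and (ii) a statistic that
separates genuinely dense inter-set connectivity from connectivity explained
by set composition alone (hubs connect to everything).

This package implements the full workflow: evidence-based inference of the
interactome with a Gaussian-kernel SVM, arithmetic for estimating how much
of the true interactome the predictions cover, the two-hypothesis GSLA
statistic, and a guilt-by-association benchmark of interactome quality. A
synthetic-fixture generator with planted functional modules makes the whole
pipeline runnable and testable with no external downloads.

## Evidence features

Six categories of evidence indicate that two genes work together:
coexpression, shared annotation terms, shared subcellular compartments,
interacting protein domains, correlated phylogenetic profiles, and
interologs (interactions transferred from orthologous pairs in other
species). The feature registry (`feature_registry()`) organizes per-pair
features into these categories with a default census of
1 + 3 + 23 + 4 + 2 + 3 = 36. The census is bookkeeping, not biology: the
exact member formulas are representative statistics per category
(correlations, Jaccard/overlap coefficients, mutual information, and a
parameterized family of domain-pair interaction aggregations crossed with
set-size normalizations for the 23-slot domain category). The registry is
pluggable, so a user with different formulas can swap them in without
touching the pipeline.

Two numerical conventions matter downstream:

* **Missing evidence is encoded as 0**, not NA. A margin classifier needs
  complete vectors; 0 is the "no evidence of association" value for every
  feature in the registry (all are non-negative or centred at 0 for
  unrelated pairs). A warning reports how many pairs were affected.
* **Term information content** is `-log2` of the term's frequency among
  annotated genes. Any monotone transform gives identical ROC AUCs, so the
  base is a display choice.

Features are screened by tie-aware Mann–Whitney ROC AUC against the gold
standard (`roc_auc()`, `select_features()`); the gate is *strictly greater
than* 0.6. The implementation reproduces the selection procedure, not any
particular published feature subset, which depended on the underlying
databases.

## Classifier

Gold-standard positives are experimentally reported protein interactions
filtered to those reported by at least two independent studies or carrying
low-throughput evidence — single high-throughput observations are too
error-prone to anchor training. Negatives are random gene pairs excluding
the positives, at 100 negatives per positive by default: most random pairs
do not interact, and the heavy imbalance keeps the false-negative
contamination of the negative class tolerable *provided true associations
are rare among all pairs* (see the generator section).

The model is a soft-margin Gaussian-kernel SVM (via e1071/libsvm, with the
kernel written as `exp(-||x-y||^2 / (2 sigma^2))`). `sigma` and the cost
`C` are grid-searched by stratified 5-fold cross-validation, maximizing the
mean per-fold harmonic mean of sensitivity and specificity. Choices the
procedure leaves open and how they are fixed here:

* **Macro-averaging across folds**: per-fold sensitivity/specificity are
  averaged, which is stable at 1:100 imbalance.
* **Stratified folds**: unstratified folds at 1:100 can lose every positive
  from a fold, making sensitivity undefined.
* **Tie-breaking** prefers the smaller `sigma`, then the smaller `C`, so the
  selected pair is invariant to grid order.
* **Default grids** are log-spaced, `sigma` in 2^-4..2^4 and `C` in
  2^-2..2^6; no grid is prescribed by the method itself.
* **Confidence** of a prediction is the absolute signed decision value
  clipped at 1: predictions beyond the unit margin score exactly 1, those
  inside the margin score proportionally lower. No probability calibration
  is applied.

Both the cross-validated and the refit-apparent sensitivity/specificity are
reported and labelled, since "training-stage" performance is ambiguous
between the two.

## Interactome size estimation

With a validated sensitivity and specificity, the number of predictions
mixes true interactions recovered at rate `sensitivity` with non-interacting
pairs leaking through at rate `1 - specificity`:

```
n_interactome * sens + (n_all_pairs - n_interactome) * (1 - spec) = n_predict
```

`estimate_interactome_size()` solves this for `n_interactome` and derives
the expected number of covered true interactions (`sens * n_interactome`)
and the expected precision of the predictions. The equation is ill-posed
when `sens <= 1 - spec` (an error), and a negative solution is reported
with a warning rather than clamped — it means the predictions are fewer
than the expected false positives alone, which is a diagnostic worth
surfacing. The all-pairs count is always an explicit input: it depends on
the gene universe, which the caller knows and this package does not. When
two sensitivity estimates are available (training-stage and
evaluation-stage), the conservative rule implemented is their minimum.

Two percentage conventions are fixed for reporting: overlap fractions round
to one decimal, support rates to two decimals, half-up.

## The GSLA statistic

For a query set `A` and reference set `B`, the inter-set density is the
number of network edges with one endpoint in each set divided by the number
of distinct unordered cross pairs, `|A||B| - k - k(k-1)/2` with
`k = |A ∩ B|`. The overlap-aware denominator is this package's definition;
the degenerate case of identical singletons has no cross pairs and is an
error.

Two criteria must both hold (defaults: density > 0.01 and permutation
p < 0.001):

* **Q1** — the density exceeds a fixed threshold, the level of background
  connectivity between unrelated sets in a genome-scale interactome.
* **Q2** — the density is higher than what networks with the *same genes
  and the same per-gene neighbour counts* produce. This controls the main
  confounder: hub-rich sets connect densely to everything.

The Q2 null is generated by degree-preserving double-edge swaps: pick two
edges `{a,b}`, `{c,d}`, replace with `{a,d}`, `{c,b}` unless a self-loop or
duplicate would result; `swaps_per_edge * n_edges` swaps are attempted per
null network (default 10, a common mixing heuristic) and every null network
is rewired afresh from the observed network with its own seeded stream, so
reference sets are tested against independent nulls. The sampler was checked
to be uniform on a fully enumerated degree-fixed ensemble. The p-value uses
the add-one (Davison–Hinkley) estimator `p = (1 + #{null >= obs}) / (1 +
n_permutations)`, which can never return 0; reaching p < 0.001 therefore
needs at least 1999 permutations, the default. Q2 is computed only for sets
passing Q1 — the criteria are conjunctive, so skipping cannot change the
reported set — and skipped sets carry `p = 1` with a `q2_tested = FALSE`
flag. One-sidedness is on density; for fixed sets this is equivalent to
one-sidedness on the raw edge count. No correction across reference sets is
applied; raw p-values are exposed so users can apply their own.

`q2_pvalue()` optionally stops permuting once the threshold decision is
settled (`early_stop_alpha`): after enough null densities reach the observed
one, `p` can no longer fall below the threshold. The decision is provably
identical to the full run (same stream, truncated); only the reported
p-value becomes a conservative estimate. This is off by default and used
where thousands of set pairs are screened.

### Exactness and conservatism of Q2

Two deliberate consequences of the estimator deserve emphasis. With `n`
permutations and the strict rule `p < alpha`, the largest rejecting p-value
is `floor(alpha * (n + 1)) / (n + 1)`; at `alpha = 0.05`, `n = 199` the
exact attainable level is 9/200 = 0.045, not 0.05. Second, the statistic is
an integer edge count: ties between the observed and null counts make any
permutation test conservative, and the deficit grows as the null
distribution narrows (the degree-conditioned count sd at desk scale is
around 10, giving an empirical level near 0.033 at nominal 0.05). Both
effects are in the safe direction — the test never over-rejects — and both
vanish in importance at the default operating point (`alpha = 0.001`,
`n = 1999`) where only the minimal attainable p rejects. The acceptance
suite measures exactly this: the empirical pass fraction on signal-free
networks stays at or below the nominal level.

## Guilt-by-association benchmark

A good functional interactome groups genes with shared function. For each
gene, biological-process terms are predicted as those over-represented
(one-sided hypergeometric, no multiple-testing correction) among the old
annotations of its first-degree neighbours, relative to the universe of
annotated genes. Sweeping the enrichment cutoff produces a
precision–recall curve: recall counts recovered *new* annotations
(annotations added after the evidence snapshot), precision counts
predictions consistent with any known annotation, old or new. Counting old
annotations in precision biases it upward — shared annotation is itself a
prediction feature — and that bias is inherited knowingly from the
benchmark this reproduces; the documentation of `pr_eval()` restates it.
The curve's AUC is the trapezoid over the observed recall span, so it
depends on the cutoff sweep; comparisons between networks are made with
the same sweep (the headline comparison is a planted-truth network against
its degree-matched rewiring, where the ranking, not the absolute value, is
the claim).

## The synthetic generator

`generate_fixture()` plants functional modules: a module's genes are
densely connected in the true interactome (`p_edge_within`, default 0.25),
share a block-exchangeable expression factor (`rho_within`, default 0.7 —
the simplest structure with controllable within/between correlation),
characteristic terms, compartments, domains with seeded interacting domain
pairs, a common phylogenetic prototype, and interolog support; each signal
is corrupted at a per-category noise rate (default 0.1). Genes beyond the
module allocation form a *background pool* with no planted signal.

The default configuration — 900 genes, 5 modules of 30, background edge
probability 1e-4, 12% of true edges carrying gold-standard records — was
chosen to reproduce the *regime* that makes 1:100 negative sampling sound
in the real application: true associations are rare among all pairs
(~0.14% here), so sampled negatives are rarely unlabeled true edges, and
module pairs are a small fraction of the universe, so membership evidence
separates held-out true edges from random pairs. Scaling the modules up to
a third of a small universe instead makes every negative-sampling batch
heavily contaminated and caps achievable ranking performance — a useful
reminder of the assumption the published regime rests on. Study-count and
throughput metadata on gold records are drawn from {1,2,3} and
Bernoulli(0.5) so the quality filter exercises all branches; the old/new
annotation split is 30% new per gene, mimicking a post-hoc annotation
snapshot without dates.

`null_fixture()` generates the matched no-signal bundle
(`rho_within = rho_between`, `p_edge_within = p_edge_between`): evidence
still has module structure but edges are independent of it, so every
feature sits at AUC 0.5 against gold labels and GSLA should pass nothing.
What passing tests on these fixtures shows: the machinery recovers planted
structure and stays at chance without it. What it does not show: performance
on real data, whose evidence is sparser, whose annotation graph is a DAG
with propagated ancestors (flat term sets here), and whose gold standards
carry correlated study biases that no independent-noise generator emulates.

## Problem sizes in the shipped checks

The package's own verification uses desk-scale experiments: a 900-gene
default bundle for classifier training (about 50 positives, 5000 negatives,
a 3x2 hyperparameter grid, three seeds), 2000 set pairs at 199 permutations
for the type-I experiment on a 400-gene null network, 20 seeded runs for
planted-module power, 10 seeds each for chance-level feature AUCs
(300-gene null bundles, ~1000 positives so each AUC carries a standard
error near 0.01) and for the paired network-versus-rewiring
precision-recall comparison. These sizes give each assertion enough
statistical resolution to fail visibly if the corresponding component is
wrong, while the whole suite stays comfortably runnable on one CPU.

## Known limitations

* The 36 feature formulas are representative members of their categories,
  not any specific published set; only the category census and the
  selection procedure are reproduced.
* No GO-graph semantics: terms are flat identifiers; information content is
  frequency-based.
* The size-estimation equation treats sensitivity and specificity as exact;
  no uncertainty interval is produced.
* `pr_eval()`'s AUC integrates over the observed recall span only, so it is
  comparable only across networks evaluated with the same cutoff sweep.
* Genome-scale all-pairs prediction is supported but not optimized (no
  kernel approximation); at 19k genes the all-pairs feature matrix and SVM
  scoring dominate runtime.
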