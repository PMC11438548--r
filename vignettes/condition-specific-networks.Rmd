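---
title: "Predicting condition-specific protein interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting condition-specific protein interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiderppi)
```

## The problem

Protein-protein interaction (PPI) assays are typically run in one
arbitrary condition, so public interactomes are static: they aggregate
interactions observed anywhere into a single "general" network that does
not tell us which interactions are actually active in a given cell type or
tissue. `spiderppi` treats condition-specific interactome construction as
a supervised edge-classification problem: given the general network (the
candidate universe), per-condition molecular profiles, and a gold-standard
condition-specific interaction map for training, predict for every
candidate edge the probability that it is active in the condition.

## Features

Each protein contributes three feature blocks:

* **Expression** — the gene's expression matrix is collapsed across
  samples by the median and min-max normalized to [0, 1] across genes
  (TPM-scale input is first transformed to `log2(x + 1)`). A binary
  missingness indicator accompanies the value, and missing values enter as
  0: the model can then distinguish "lowly expressed" from "not measured".
  The choice to normalize after the median collapse (rather than per
  sample) keeps the feature a property of the condition, not of a
  replicate.
* **Abundance** — protein-abundance profiles, median-collapsed and
  min-max normalized the same way (no log step), with the same
  missingness convention.
* **Localization** — a probability vector over a fixed ordered set of
  cellular compartments (63 for the human annotation universe): mass
  `1/k` on each of the protein's `k` annotated compartments, the zero
  vector for unannotated proteins.

Each candidate edge contributes:

* **Co-abundance** — the Pearson correlation of the two endpoints'
  abundance profiles across samples. Correlations are total functions
  here: fewer than 3 shared samples, or zero variance in either profile,
  yield 0. This keeps every feature bounded and defined rather than
  propagating NAs into the model.
* **Co-localization** — the Pearson correlation of the two localization
  vectors, with the same zero fallback for constant (including all-zero)
  vectors. Two proteins annotated to disjoint single compartments out of
  63 get `-1/62`, the exact correlation of disjoint one-hot vectors.
* **Detection techniques** — an 11-category count vector of the assay
  classes in which the interaction was reported, with a terminal
  "other" category absorbing unknown assay names. Counts are `log1p`
  transformed before entering the classifier (raw counts span orders of
  magnitude; the transform keeps the block on the scale of the other
  features). The block can be disabled wholesale for organisms whose
  assay provenance is uninformative.

## The model

Candidate edges are scored by a neural network implemented natively in R
(plain matrix algebra with a hand-written backward pass, verified against
numerical differentiation in the test suite):

1. **Projection blocks.** Each node feature block is projected into a
   joint embedding space by its own two-layer feed-forward block (ReLU
   after the first layer, dropout inside, linear second layer). The three
   projections are summed.
2. **Graph attention.** One attention layer over the general network
   (self-loops included) aggregates each protein's neighborhood:
   attention logits are leaky-ReLU scores of linear forms in the source
   and target embeddings, normalized per target by a softmax. A residual
   connection adds the projected features back to the attention output.
   The residual is an engineering choice the architecture needs at this
   depth: a single content-based attention layer cannot upweight the
   self-loop specifically, so without the skip the aggregation smooths
   per-protein expression into a neighborhood average and the expression
   signal is unlearnable. The directed message list is kept in a canonical
   (target, source) order so the forward pass is bit-for-bit invariant to
   how input edges were oriented or sorted.
3. **Deep-set pair merger.** For a queried edge, both endpoint embeddings
   pass through one shared FC layer (phi), the outputs are **summed** —
   the order-invariant step that makes the score exactly symmetric under
   endpoint exchange — and the sum passes through two FC layers (rho).
4. **Head.** The pair embedding is concatenated with the raw edge
   features (co-abundance, co-localization, technique counts) and scored
   by three FC layers ending in a sigmoid, giving the probability that
   the edge is active in the condition.

All hidden widths are tied to the embedding size `d`: projections and the
attention layer map to `d`, phi and rho stay at `d`, and the head runs
`d + 13 -> d -> d/2 -> 1`.

## Training protocol

* **Node-based split.** Nodes are partitioned 70/15/15 into
  train/validation/test; an edge belongs to a split only if *both*
  endpoints do. Cross-split edges belong to no split. This evaluates
  generalization to unseen proteins, not just unseen pairs.
* **Message-passing scope.** During training the attention layer sees
  only the subgraph induced by train+validation nodes; at prediction
  time it sees the full general network. This prevents test-node
  neighborhoods from leaking into training and is configurable.
* **Optimization.** Adam (learning rate `1e-3`, weight decay `0.01`),
  binary cross-entropy, 750 epochs, dropout 0.3 in the feed-forward
  blocks, embedding size 64 — the selected configuration of the tuning
  grid (`default_grid()` spans embedding {32, 64, 128}, learning rate
  {1e-3, 5e-4, 1e-4}, dropout {0.2, 0.3, 0.4}, epochs {500, 750, 1000};
  `tune_spider()` selects by validation AUPRC, which is the right
  currency under heavy class imbalance). Each epoch is run as two
  shuffled mini-batches rather than one full batch: at a fixed epoch
  budget this doubles the number of optimizer steps, which the training
  needs to reach the feature ceiling on the benchmark below; the batch
  count is a hyperparameter (`batches = 1` restores full-batch).
  Weights use He-normal initialization, matching the ReLU activations.
* **Determinism.** One integer seed fixes the split, the initialization,
  the batch shuffles and the dropout masks; two runs with the same seed
  produce bit-identical models.
* **Class imbalance** is handled by plain (unweighted) cross-entropy;
  evaluation leans on AUPRC next to AUROC.

`train_spider_combined()` trains one model jointly on several conditions
over the same candidate universe (each condition contributes its own
features and labels for the pooled train edges) — the construction used
to build networks for conditions that have profiles but no gold standard.

## Transfer learning

`fine_tune_spider()` adapts a trained model to a data-poor condition: the
per-feature projection blocks (the protein-level layers) are frozen and
the remaining layers continue training on a chosen fraction of the target
train edges, at learning rate `5e-4` for 100 epochs — deliberately gentle
to avoid overfitting small targets. The packaged transfer benchmark pairs
a source condition generated under the default planted rule with a target
whose rule adds a detection-technique component the source rule lacks
(`expression 2, colocalization 0.5, coabundance 1, technique 3`). The
geometry matters: when source and target rules share all their
components, a model trained on the source already ranks sibling
conditions near their ceiling and a few hundred extra edges add only
noise — fine-tuning then *hurts* slightly. The value of transfer is
measurable exactly when the target depends on a signal the source model
learned to ignore; correcting that is a low-dimensional adjustment of
the classifier head that a 10% sample teaches reliably.

## Baselines

* **Node removal (NR):** keep nodes with normalized expression at or
  above a threshold and the edges among them (score 1), drop the rest
  (score 0).
* **Edge reweighting (ERW):** multiply each edge weight by `rw^n`, `n`
  the number of endpoints below the expression threshold, with the
  conventional penalty `rw = 0.001`. At `rw = 1` it reduces to the input
  weights; its score equals the input weight exactly when NR retains the
  edge — the two definitions are consistent by construction.
* **Calibrated co-abundance:** rank edges by abundance-profile Pearson
  correlation, then map correlations to probabilities with a univariate
  logistic model whose labels are co-membership in an annotated protein
  complex. The monotone link preserves the ranking; calibration only
  makes scores comparable across datasets.

Because NR and ERW have no intrinsic ranking (they depend on the chosen
expression threshold), their curve areas are computed by sweeping the
threshold over the observed expression values: each edge's composite
score is the mean of its per-threshold score across the grid (survival
frequency for NR, mean reweighted score for ERW), and that ranking is
scored by the package's own AUROC/AUPRC. When a single binary network is
needed instead, the threshold is fixed by F1 maximization.

## Evaluation

`auroc()` is the Mann-Whitney statistic (ties get half credit), identical
to the trapezoidal ROC area. `auprc()` is the step-wise, non-interpolated
PR area with tied scores processed as one block; with all scores equal it
degenerates to the positive rate, as it should. `select_threshold()`
scans observed scores for the F1 maximizer and resolves ties toward the
smallest threshold. `generalization_matrix()` applies each condition's
model to every other condition's labeled edges; diagonal entries are left
absent because within-condition performance is measured on held-out
splits instead.

## Downstream analyses

* **Condition networks.** `build_network()` runs one forward pass over
  all candidate edges with a condition's (median-collapsed) features.
  The default probability threshold for the unweighted version is 0.39,
  carried over from F1 maximization on held-out cell-line data in the
  protocol this package implements; it is a parameter everywhere.
* **Ontology coherence.** Pairwise network distance is the Pearson
  distance `1 - r` between probability vectors; tissue distance is the
  sum of path lengths to the lowest common ancestor in a tissue-ontology
  tree. `ontology_correlation()` correlates the two across all tissue
  pairs (at least 3 tissues; one pair has no correlation).
* **Degree enrichment.** For each protein, the change in degree
  percentile (mid-rank ties over the full protein universe; absent nodes
  have degree 0) between the thresholded condition network and the
  general network; tissue-annotated proteins are compared against the
  rest with a two-sided Wilcoxon rank-sum test (normal approximation
  with continuity correction when both groups have at least 20 members,
  exact otherwise). Sets with fewer than 25 annotated proteins in the
  network are skipped. P-values are reported per tissue without
  multiple-testing correction, matching the per-tissue reporting
  convention; callers can correct across tissues themselves.
* **Propagation.** `propagate()` iterates
  `s <- alpha * W s + (1 - alpha) * p0` to its fixed point, with
  `W = D^-1 A` the row-stochastic (degree-normalized) weighted adjacency,
  `p0` uniform over seed genes, `alpha = 0.8`, convergence tolerance
  `1e-8`, at most `1e4` iterations. "Stochastic normalization" admits a
  symmetric reading too, so `normalization = "symmetric"` is offered.
  `cv_disease_genes()` evaluates a gene set by 3-fold cross-validated
  propagation, excluding seed genes from the evaluated ranking (standard
  leakage control) and skipping sets under 25 usable genes.
* **Consensus networks.** For sample-resolved datasets, co-abundance for
  one sample is computed over the sample plus its 5 most cosine-similar
  samples; per-sample networks are averaged edgewise into a consensus.
  `score_drivers()` propagates each sample's mutated gene set (point
  mutations and copy-number alterations as one set) and averages over
  samples; `driver_enrichment()` reports the top-K enrichment
  `(n/K) / (|gold|/N)`.

## The synthetic benchmark

`synth_config()` plants a recoverable condition-specific rule into fully
synthetic data so every pipeline stage is testable without external
downloads. Defaults: 600 proteins, 5000 candidate edges, 5 samples per
condition, 63 compartments, conditions on a balanced binary similarity
tree. Per condition, a latent expression level per gene follows a
Gaussian walk along the tree (branch sd 0.6), expression replicates are
drawn around it, and abundance replicates share per-module latent sample
factors (30 modules of 20 proteins) so co-module pairs are strongly
co-abundant. The planted edge-activity logit is

```
3 * min(expression of endpoints) + 2 * max(colocalization, 0)
  + 2 * same_module + Normal(0, 0.25)
```

thresholded at the 85th percentile (15% positives), with 2% of labels
flipped. The co-localization and co-abundance components are invisible to
expression-only baselines by construction, so a supervised model that
uses all features has a demonstrable advantage; the noise and label flips
keep the ceiling below perfection (a logistic model on the noiseless rule
inputs reaches roughly 0.93 AUROC at this scale). Sibling conditions
share more gold edges than conditions across the root, which the
ontology-coherence checks rely on.

What the generator does **not** emulate: realistic degree distributions
(a power-law option exists but the default is uniform), correlated
assay-count structure, batch effects, or biases of curated interactomes.
Green tests on this benchmark demonstrate that the implementation
recovers a planted signal of the intended shape at realistic noise — not
that the model attains any particular performance on real interactomes.

## Problem sizes and numerical choices

The test suite trains on the default 600-protein/5000-edge benchmark for
the headline checks (three seeds) and on 60-150-protein worlds for
contract tests; these sizes keep the full suite under ten minutes on one
CPU while leaving AUROC estimates stable to within a few points.
Backpropagation is verified against central finite differences at
tolerance 1e-4 (biases perturbed away from zero so no ReLU pre-activation
sits exactly on its kink, where one-sided derivatives differ). Propagation
is verified against the closed-form solve `(I - alpha W)^-1 (1-alpha) p0`
to 1e-6. All Pearson-degenerate cases (constant vectors, too few samples)
return 0 by contract rather than NA.

## Limitations

* The attention layer is single-head and single-layer; deeper stacks
  would need their own leakage and over-smoothing analysis.
* Technique counts are treated as fixed exogenous features; no attempt
  is made to model assay reliability explicitly.
* The logistic co-abundance calibration uses the correlation as its only
  covariate; richer calibration models exist but are underdetermined
  here.
* Gold-standard maps are taken at face value: label noise in real
  condition-specific interactomes (and text-mining-derived ones in
  particular) directly bounds achievable and measurable performance.
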