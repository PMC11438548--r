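# spiderppi

Supervised prediction of condition-specific protein–protein interaction
(PPI) networks.

## The problem

PPI detection assays are run in one arbitrary condition, so public
interactomes are *static*: they pool every interaction ever observed into
one "general" network and say nothing about which interactions are active
in a particular cell type or tissue. Where gold-standard
condition-specific interaction maps exist, the construction of new
condition networks can be posed as supervised edge classification: given
the general network as the candidate universe and a condition's molecular
profiles, predict for each candidate edge the probability that it is
active in that condition. This package implements such a classifier, the
classical unsupervised comparators, and the downstream analyses that
condition networks enable (disease-gene prioritization by network
propagation, driver-gene enrichment, tissue-ontology validation).

## The model

For each protein *v* the model ingests normalized gene expression
`x_v ∈ [0,1]`, normalized protein abundance `a_v ∈ [0,1]` (each with a
missingness flag) and a localization probability vector `ℓ_v` over 63
cellular compartments. Each block is projected by its own two-layer
feed-forward network into a joint space and summed:

    z_v = FF_expr(x_v) + FF_abund(a_v) + FF_loc(ℓ_v)

One graph-attention layer over the general network *G* (self-loops
included, residual connection) aggregates neighborhoods:

    h_v = ReLU( Σ_{u∈N(v)∪{v}} α_uv W z_u + b + z_v ),
    α_uv = softmax_u( LeakyReLU(a_s·Wz_u + a_t·Wz_v) )

A deep-set merger scores a candidate edge (u, v) order-invariantly —
`ρ(φ(h_u) + φ(h_v))` with φ one FC layer and ρ two — and the result,
concatenated with the edge features (co-abundance `corr(a_u, a_v)`,
co-localization `corr(ℓ_u, ℓ_v)`, 11 detection-assay counts), passes
through a three-layer head with a terminal sigmoid:

    p(u,v active) = σ( head[ ρ(φ(h_u)+φ(h_v)) ‖ edge features ] )

Training: Adam (lr 1e-3, weight decay 0.01), binary cross-entropy,
750 epochs, dropout 0.3, embedding size 64, on a **node-based** 70/15/15
split (an edge belongs to a split only if both endpoints do). The whole
network — forward pass, backpropagation, Adam — is implemented natively
in R and the gradients are verified against numerical differentiation in
the test suite. Everything is deterministic given one seed.

Also included:

* **Baselines** — node removal (NR), edge reweighting (ERW, `rw^n`
  penalty with `rw = 0.001`), and logistic-calibrated co-abundance.
* **Transfer learning** — freeze the protein-level projection blocks and
  fine-tune the rest on a fraction of a new condition (lr 5e-4,
  100 epochs).
* **Propagation** — random walk with restart
  (`s ← αWs + (1−α)p₀`, row-stochastic `W`, α = 0.8) with 3-fold
  cross-validated disease-gene scoring.
* **Consensus networks** — per-sample networks (co-abundance over a
  sample's 5 nearest neighbors by cosine similarity) averaged edgewise;
  top-K driver enrichment `(n/K)/(|gold|/N)`.
* **A synthetic-data generator** — complete inputs with a planted,
  recoverable condition-specific rule, so everything above is testable
  offline (see the methods vignette in `vignettes/`).

## Worked example

```r
library(spiderppi)

# a synthetic world with a planted condition-specific interaction rule
cfg  <- synth_config(n_proteins = 150, n_edges = 900, seed = 42)
net  <- generate_general_network(cfg)
cond <- generate_condition(cfg, net, 1)
ds   <- assemble_dataset(net, cond$profile, cond$annotations,
                         cond$compartments)

split <- split_nodes(net, seed = 42, labels = ds$labels)
model <- train_spider(ds, split, spider_hyperparameters(epochs = 300),
                      seed = 42)

te <- split$test_edges
eval_report(predict(model, ds, edges = te), ds$labels[te])

ex <- normalize_expression(cond$profile$gene_expression, cond$profile$scale)
sweep_threshold(net, ex, ds$labels, "nr")$auroc
cn <- build_network(model, ds, threshold = 0.39)
```

Output:

```
general_network: 150 nodes, 900 edges
spider_dataset 'cond_1': 150 nodes, 900 candidate edges, positive rate 0.159
AUROC 0.9176 | AUPRC 0.8333 | positive rate 0.2273 | best F1 0.7500 at 0.4193
NR  swept AUROC: 0.7162
ERW swept AUROC: 0.7163
condition_network 'cond_1': 900 edges, 90 above threshold 0.39
```

Reading this: 15.9% of the 900 candidate edges are active in this
condition. On the held-out test edges (edges whose *both* endpoints the
model never trained on; 22.7% positives there) the trained model ranks
active edges at AUROC 0.92 / AUPRC 0.83, versus 0.72 for the
expression-threshold baselines — the planted rule's co-localization and
co-abundance components are invisible to them by construction. The F1
maximizing probability cutoff (0.42 here) is how a binary network would
be thresholded; at the default threshold 0.39 the predicted
condition-specific network keeps 90 of 900 candidate edges.

A command-line front end over the same functions lives at
`inst/cli/spider.R`
(`Rscript inst/cli/spider.R simulate|train|predict|baseline|eval|propagate|enrich ...`).

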