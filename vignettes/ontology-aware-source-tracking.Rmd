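---
title: "Ontology-aware microbial source tracking: model, design, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-aware microbial source tracking: model, design, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontosource)
```

## The model

A microbial community sample is represented by its community structure:
taxa at the seven standard taxonomic levels (super-kingdom through genus)
with their relative abundances. Candidate source biomes form a rooted
ontology `O`: layer 1 is `Root`, and each deeper layer refines its parent
(`Root-Host_associated-Human-Digestive_system-Oral-Saliva` is a layer-6
biome). Source tracking is cast as hierarchical multi-label prediction:
the network learns a mapping from a sample `s` to per-layer source biomes
`x_s = (x_s^2, ..., x_s^L)` with source contributions
`y_s = (y_s^2, ..., y_s^L)`, one contribution in (0, 1) for every ontology
node. At query time the argmax node per layer is reported as the layer's
source, the full vector as the contribution profile, and
`max(0, 1 - sum(layer contributions))` as the layer's unknown mass.

The working assumption, which the simulator makes explicit, is that
samples from the same biome share a compositional signature and that
signatures are correlated along ontology edges more than across them.
Everything the package infers degrades gracefully with that correlation:
when bottom-layer niches are not separable, mass concentrates on the
(still separable) upper layers rather than being forced into a wrong leaf.

### Sample representation

Each sample is an N × 7 matrix over a frozen feature vocabulary: one row
per taxon-at-a-level, one column per taxonomic level, so a row is non-zero
only in its own level's column. Abundances are re-normalized to sum to 1
per level over the taxa assigned at that level; records lacking a rank
contribute nothing at that rank. This per-level re-normalization is a
design choice — the alternative (normalizing once over all records) makes
levels with poor rank coverage systematically lighter, which would leak
profiler coverage into the classifier. Taxa unseen by a trained model's
vocabulary are dropped with a warning rather than an error, because a
frozen model cannot grow rows at query time. The matrix is flattened
row-major (7N) at the network input, preserving each cell's level
identity.

Lineage strings use the dominant profiler dialect: rank-prefixed tokens
(`sk__`, `k__`, `p__`, `c__`, `o__`, `f__`, `g__`) joined by `;`. Ranks
below genus are ignored. Biome lineages use `-` as the layer separator,
which is therefore reserved: biome labels containing `-` are rejected, and
the packaged synthetic lineage list renames the one MGnify-style biome
that would violate this (`Non_marine_Saline_and_Alkaline`).

### Ontology construction

The ontology is built from lineage strings by prefix closure: every
prefix of every listed lineage is a node. A biome occurring under k
distinct parents yields k distinct nodes (so the structure is always a
tree), and a label-to-nodes index lets `biome_total()` sum a split biome's
contribution back together. Node order within a layer is lexicographic by
full lineage — the ordering is arbitrary in principle, but model heads,
score matrices and truth matrices all need one fixed index map, so it is
part of the contract. Ontologies of any depth are accepted; layer 1 must
be `Root`.

The packaged lineage list (`inst/extdata/biome_lineages_synthetic.tsv`) is
a synthetic reconstruction of an MGnify-style inventory: 133 nodes in 6
layers (1/4/7/22/56/43 per layer) representing 114 biomes, with per-biome
sample counts totalling 125,823 and the documented niches (Throat with 22
samples, Saliva, Groundwater, Petrochemical wastewater, `Root-Mixed` as the
fourth layer-2 node, ...) present verbatim. Its header states that it is
not an original supplementary table; tests that use it check that the
builder reproduces this structure, not that any external inventory
round-trips.

### Network architecture

Four functional stages, all fully connected:

1. **feature extractor**: 7N → `d_ext`, ReLU; shared by all layers;
2. **per-layer encoders**: `d_ext` → `d_enc`, ReLU, one per ontology layer
   2..L;
3. **per-layer incorporators**: ReLU maps combining the layer's encoding
   with the incorporated state of the layer above,
   `inc_i = relu(W [enc_i ‖ inc_(i-1)])`, with `inc_1` defined as the
   extractor output. This wiring is a design decision: the incorporator's
   role is inter-layer information flow, and chaining the incorporated
   state top-down is the simplest architecture that gives deeper layers
   access to what the shallower layers saw;
4. **per-layer heads**: `d_enc` → (number of nodes at layer i), sigmoid.
   Head outputs are read directly as source contributions.

Sigmoid heads rather than a softmax are deliberate: contributions are not
forced to sum to 1 per layer, mixtures keep several active nodes, and the
per-layer unknown mass is computed from the shortfall. Raw sigmoid outputs
are reported as contributions without renormalization; the unknown-mass
convention makes the shortfall explicit instead of hiding it in a
normalizer.

### Loss and training

Per sample, the loss is the sum over layers 2..L and over nodes of binary
cross-entropy against the one-hot ancestor path of the sample's biome,
plus an ontology-consistency hinge `lambda * sum over edges of
max(0, child - parent)`. BCE matches the sigmoid heads; the hinge
operationalizes the requirement that predictions respect the ontology — a
child niche cannot have contributed more than its parent habitat. `lambda`
defaults to 0.1 (0 disables it); trained toy models satisfy
`parent >= child - 0.05` on at least 95% of edges on held-out data, which
is tested as a soft property.

Optimization is hand-rolled minibatch Adam (learning rate 1e-3, batch 512)
with exact gradients, including the hinge term — the backward pass is
verified against central finite differences in the test suite. Training
runs for at most 30,000 iterations; training accuracy (mean over layers of
argmax accuracy) is evaluated every 10 iterations, the best-accuracy
checkpoint is kept, and training stops early once the best accuracy has
not improved by more than 1e-4 for 500 consecutive iterations. The 8-fold
protocol splits the data into 8 seeded folds (87.5% train / 12.5% test
each). Hidden widths default to `d_ext` 256 and `d_enc` 128 and are
configurable; the synthetic benchmark uses 64/32, which is proportionate
to its 60-taxon vocabulary.

All randomness — initialization, batching, fold assignment, simulation —
is seed-controlled, and identical seeds reproduce identical weights,
histories, and datasets bit for bit.

### Feature selection

Two sequential stages, each with per-level adaptive thresholds:

1. **abundance pre-filter**: within level l, keep features whose mean
   relative abundance is strictly above `C * mean(level-l means)`;
2. **importance selection**: fit a random-forest regression from the
   survivors to the one-hot bottom-layer label matrix (one regression
   forest per biome column, impurity importances averaged), then keep
   features strictly above `C * mean(level-l importances of survivors)`.

`C = 0.001` by default. Strict `>` at both stages makes the boundary
behavior definite (a level of all-zero features keeps nothing). One-hot
regression is the standard reconciliation of a regression forest with
categorical labels; the per-class forests are seeded deterministically.
Two conventions were genuinely open and are fixed as follows: the level
mean `R̄_l` averages over **all** features at level l (not only non-zero
ones), and the importance mean `Ī_l` averages only over pre-filter
survivors, because the stages are sequential. The pre-filter is provably
monotone in C (larger C never keeps more), which the tests exercise.

### Evaluation suite

For a sample i and threshold t, the predicted set `P_i(t)` contains the
nodes scoring strictly above t; the actual set `T_i` is the label's
ancestor node at the evaluated layer. Sweeping t from 0 to 1 in steps of
0.01 gives per-biome confusion counts, from which follow per-biome and
macro TPR/FPR curves, macro precision/recall/accuracy, F_max, and the
trapezoidal AUC over the swept (FPR, TPR) points augmented with (0,0) and
(1,1). Conventions, each a deliberate choice where the formulas leave 0/0
undefined:

- biomes with no positive samples are excluded from the macro TPR mean,
  biomes with no negatives from the macro FPR mean;
- precision is undefined (and excluded from its mean) for biomes never
  predicted at t; F_max averages over biomes that are actual **and**
  predicted at least once at that t;
- reported accuracy is the macro mean over biomes of the per-biome
  accuracy formula;
- strict `>` membership makes the sweep well-defined at both ends (t = 1
  is empty under sigmoid scores);
- macro (not micro/pooled) averaging is the default throughout, matching
  the per-biome-then-mean structure of the curve definitions.

Every metric is validated against an independent exhaustive-enumeration
oracle (plain loops over thresholds, biomes, and samples) to 1e-12 on
1,000 random small instances, and the AUC anchors — 1.0 for perfect
separation, 0.5 for constant scores, 0.5 ± 0.03 on a 5,000-sample
Monte-Carlo null — are asserted directly.

Flat per-leaf predictions from non-hierarchical methods are lifted to all
layers by `remold_flat()` / `remold_scores()`, which reuse the exact
child-sum aggregation, so external methods can be scored on the same
hierarchical footing. The package deliberately does not re-implement those
methods.

## The simulator

`make_signatures()` draws, per taxonomic level, a root composition from a
symmetric Dirichlet (concentration 0.8 by default — sparse, skewed
profiles) and propagates it down the tree as
`child = renormalize((1 - drift) * parent + drift * fresh)`; `drift = 0`
copies the parent everywhere, `drift = 1` severs the correlation.
`sample_dataset()` observes each bottom-layer signature through Dirichlet
noise with precision `noise_concentration` (mean preserved, variance
shrinking as precision grows). `mix_sources()` blends leaf signatures with
known weights and carries the exact aggregated per-layer ground truth.
Dirichlet draws use the standard gamma construction.

The benchmark configuration — complete `[2, 4]` ontology (8 leaf niches
under 2 habitats), 60-taxon vocabulary, 150 samples per leaf, drift 0.4,
precision 50, seed 7, 8-fold protocol — was chosen once as a realistic
mid-difficulty regime: drift 0.4 leaves sibling niches clearly related to
their habitat yet separable, and precision 50 puts sample noise in the
range of technical-replicate variability. On it the trained network
reaches held-out bottom-layer macro AUC and argmax accuracy above 0.99
(assessed over all 8 folds, 1,200 held-out predictions in total).

What the simulator does **not** emulate: real taxon frequency spectra
(long-tailed, zero-inflated), cross-level constraints (a genus's abundance
summing into its family's — levels are generated independently),
compositional artifacts of profiling pipelines, or batch effects. Passing
the synthetic benchmark therefore demonstrates that the machinery —
representation, training, hierarchical evaluation — is correct and that
the model can exploit parent-correlated signatures; it does not certify
accuracy on any real corpus.

## Numerical choices and degenerate inputs

- Sigmoid/BCE clipping at 1e-7 keeps the loss finite at saturated outputs.
- Argmax ties break toward the lower node index (first in lexicographic
  layer order); with all-zero weights every output is exactly 0.5 and the
  strict threshold excludes everything from predicted sets.
- Upward aggregation computes each parent as `sum()` over its children in
  node order, so conservation is exact (bitwise), not approximate; the
  tests assert identity, not tolerance.
- Empty datasets, single-class label sets, out-of-range layers, malformed
  lineages, negative abundances, vocabulary/ontology hash mismatches, and
  truncated or version-mismatched model bundles all fail fast with
  specific errors rather than propagating NA.
- Model bundles verify a format tag and the vocabulary/ontology hashes on
  load; a reloaded model reproduces forward outputs bit-identically.

## Problem sizes used by the shipped checks

Unit tests train small networks (tens of features, hundreds of samples,
hundreds of iterations); the benchmark trains 8 folds of 1,050 samples for
as long as the convergence rule demands (typically under 1,000 iterations
each); the metric-oracle sweep uses 1,000 instances of at most 30 samples
and 6 biomes; conservation is checked on 1,000 random trees of depth up to
6. These sizes were picked so the full suite documents the package's
behavior in minutes while still exercising every code path at non-trivial
scale.

## Known limitations

- Contributions are independent sigmoids: they need not sum to 1 within a
  layer, and calibration of the absolute values is not enforced — rankings
  and thresholded sets are the reliable outputs.
- The consistency hinge is a soft penalty; ontology violations are
  discouraged, not impossible.
- Feature selection targets bottom-layer separability only; features that
  matter solely for upper-layer distinctions are kept only insofar as they
  correlate with leaf labels.
- Mixture quantification is supported by the simulator and the profile
  representation, but training uses single-source labels; recovering
  mixture weights from a model trained on pure samples is approximate.
- The CLI trains on a single data set per invocation; cross-validated
  protocols are driven from R (see `split_folds()`).
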