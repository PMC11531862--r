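---
title: "Methods: multi-task graph learning for protein localization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-task graph learning for protein localization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtloc)
```

## The problem

A protein's subcellular localization (SL) is a multi-label property — one
protein can occupy several compartments — and it is strongly coupled to the
protein's function: what a protein does constrains where it must be.  gtloc
implements a multi-task collaborative model that learns Gene Ontology (GO)
function prediction (the three sub-ontologies BP, CC, MF) as auxiliary tasks
and feeds the learned functional features into the localization head, rather
than looking function annotations up in a database at prediction time.

The input per protein is (i) its sequence, (ii) the 3D positions of its
alpha carbons (from any structure source: experimental files or a structure
predictor), and (iii) a per-residue embedding matrix from a pluggable
provider.  Real deployments would plug a protein language model in through
`table_embedding_provider()`; the package ships a synthetic Gaussian
provider so that everything is testable offline.

## Model

### Residue contact graph

Residues are nodes; an undirected edge connects every pair of alpha carbons
at distance <= 4.5 Å (inclusive).  Edge features (42 dimensions by default)
concatenate the Ca distance, a sine/cosine encoding of the displacement
vector at geometric frequencies {1, 1/2, 1/4, 1/8} rad/Å, the flattened
displacements from the source residue to its five spatially nearest
residues (zero-padded for very short chains), and the summed neighbour
distances of both endpoints.  Two design choices here favour invariance:
the sine/cosine encoding is applied to the
*displacement* (not absolute coordinates) so every edge feature is
translation invariant, and the five-nearest-neighbour block is attached
per-edge as displacements from the source node.  Nearest-neighbour ordering
compares distances at 1e-8 Å resolution with residue-index tie-breaks, so
exact ties (e.g. the two chain neighbours at identical bond lengths) are
resolved deterministically and survive rigid motions of the coordinates.

### Graph transformer (GT) encoder

Node and edge features are first projected to width `d_p` by two linear
layers.  Each of the `n_layers` transformer layers then runs multi-head
attention restricted to contact edges.  For head `k` and edge `(i, j)` the
attention score is the channel-wise product

    s_ij = (Q_i * K_j) / sqrt(d_k) * E_ij,

with the softmax taken over the neighbours `j` of `i` independently per
channel.  This channel-wise reading is the only one under which the
concatenated attention weights have width `h_d * d_k = d_p`, as required by
the `d_p x d_p` edge-update map (the same resolution used by
edge-featured graph transformers in the Dwivedi–Bresson style).  Node
messages are attention-weighted sums of `V_j`; edges are updated from the
concatenated attention weights.  Both streams then pass residual
feed-forward blocks (expand to `2 d_p`, SiLU, contract) with batch
normalization on the sublayer inputs.  Batch statistics are used in
training and running statistics (momentum 0.1) at inference, so prediction
is deterministic and independent of batch composition.  Self-loops are not
added: the neighbourhood is exactly the contact map, and the residual
stream already preserves self-information.  A single shared normalization
per layer feeds Q, K and V; dropout is not used.

Nodes with no neighbours receive a zero attention message and pass through
the residual paths.  Attention score stabilisation subtracts the
per-(node, head, channel) maximum before exponentiation.

### Ontology branches: projection, graph autoencoder, score heads

Each ontology (BP, CC, MF) owns an independent parameter set.  The branch
applies two stacked affine maps with no interleaved activation (kept as
two parameterized layers for architectural clarity, although the
composition is mathematically affine), then one graph-convolution encoder layer

    H_fun = LeakyReLU(D^-1/2 (A + I) D^-1/2  H W),

with negative slope 0.01.  A graph autoencoder decodes the adjacency by
inner products, `Ahat = sigmoid(H H^T)`, and contributes a reconstruction
loss: the mean squared error over all n^2 entries against the adjacency
with self-loops.  The mean is taken over all n^2 entries (a row-wise mean would differ
only by a constant factor that the loss weight beta absorbs).  Including the diagonal keeps the target consistent
with the `A + I` the encoder normalizes.

Function scores pass the branch features through self-attention pooling and
a two-layer MLP (hidden width `d_fe`, ReLU, sigmoid outputs) over the
ontology's vocabulary.

### Self-attention pooling

A one-layer graph convolution scores every node; the top `ceil(r * n)`
nodes are kept (ties toward the lower residue index), their features are
gated by `tanh(score)`, and the readout concatenates the mean and max over
kept nodes.  This is the SAGPool-style reading of "self-attention pooling
with node masking", fixed here in its concrete, widely used form.  Each use
site (three ontology heads and the localization head) owns independent
pooling parameters.  The raw node scores of the localization pooling layer
double as the per-residue importance signal: min–max normalized within one
protein (constant scores map to 0.5 by convention), they are exported for
comparison with, e.g., annotated functional domains.

### Functional cross-attention and the localization head

Each branch output first passes an ontology-specific two-layer MLP
(`nlinear`).  Three independent attention groups then run dense multi-head
attention over the protein's own residues, with queries projected from the
BP features, keys from MF and values from CC — deliberately asymmetric:
the process branch interrogates molecular function, and component
features carry the values.  Attention here is dense within the protein
(the architecture states no edge restriction for this block).  The three
group outputs are averaged node-wise ("mean" is read as averaging the three
feature tensors, not averaging over nodes, since the result must remain a
per-node tensor), projected by `O^t` with ReLU, and refined by a residual
feed-forward block expanding to `2 d_F` and contracting back, the standard
transformer form.  The
localization head is self-attention pooling plus a two-layer MLP with
sigmoid outputs over the localization classes.

### Collaborative loss

With multi-label BCE losses for the three GO tasks and localization, and
the three reconstruction MSEs,

    L = alpha * (L_bp + L_cc + L_mf)
      + beta  * (L_bp_mse + L_cc_mse + L_mf_mse)
      + omega * L_sl.

Predictions are clamped to `[1e-7, 1 - 1e-7]` inside the BCE for numerical
safety.  Per-batch losses are weighted by batch size so the logged epoch
loss equals the full-dataset value.  The weights default to
`alpha = omega = 1`; `beta = 0.2` is the package default because the
reconstruction target (geometry) competes with the function signal for the
same `d_fe` feature channels, and equal weighting measurably slows the
auxiliary-task learning on synthetic data; the weights are exposed for
tuning at other scales.

### Ablation variants

Four config flags reroute the forward or loss exactly:

* `no_gt` — skip the transformer layers (input projection only);
* `no_feaE` — bypass the GAE encoder (branch projections feed the heads
  directly) and force `beta = 0`;
* `no_funA` — replace cross-attention + fusion by the elementwise sum of
  the three `nlinear` outputs followed by the `O^t` projection and FFN;
* `no_colT` — zero `alpha` and `beta` in the loss only (predictions are
  unchanged; only localization supervises training).

## Training

Adam (lr 1e-4 by default for full-scale data, beta1 = 0.9, beta2 = 0.999)
over mini-batches of proteins merged as disjoint graphs (block-diagonal
adjacency; batch-norm statistics span the batch).  Default 50 epochs.
Optional decoupled (AdamW-style) weight decay, a cosine learning-rate
schedule with warmup, and global gradient-norm clipping are exposed in the
configuration; all default off.  At desk scale (a few hundred training
proteins) weight decay around 5e-4 measurably closes the train/test gap on
the GO tasks and is used by the shipped experiments.  Validation
localization AP selects the retained checkpoint.  The seed controls parameter
initialization, data order and synthetic generation; two runs with the same
seed produce identical loss curves.

All tensor operations run on a small reverse-mode autodiff tape written in
base R (`R/autograd.R`), validated against central finite differences
through the complete forward pass.  Weights use Glorot-uniform
initialization, `U(±sqrt(6/(fan_in + fan_out)))`: the architecture is
dominated by affine sublayers (branch projections, nlinear, fusion, heads),
and gain-2 fan-in scaling compounds roughly 2x variance per sublayer, which
saturates the sigmoid heads at initialization; Glorot keeps initial scores
near 0.5.

## Synthetic data

The generator produces the statistical structure the model assumes, at desk
scale:

* **Backbones** — fixed-step (3.8 Å, the trans Ca-Ca distance) self-avoiding
  random walks with a 3.6 Å excluded-volume radius; consecutive residues are
  always in contact at the 4.5 Å threshold, and chain folding creates
  non-local contacts.
* **Embeddings** — i.i.d. standard normal per residue, dimension 16 by
  default.
* **Motifs** — per GO term, a contiguous window of `k` residues (default 8)
  shifted by magnitude `mu` along a term-specific random unit direction.
  GO labels record motif presence (default prevalence 0.3).  Contiguity
  mirrors the fact that functional domains occupy residue ranges, which is
  what makes per-residue importance scores interpretable.
* **Localization** — each SL class is a small OR-of-ANDs boolean formula
  over GO terms (default: 4 classes over 8 BP / 5 CC / 5 MF terms), flipped
  independently with probability `noise_rate` (default 0.05).  This encodes
  the premise that localization is a noisy function of function.

What the generator does **not** emulate: realistic protein geometry (no
secondary structure), language-model embedding geometry, GO term
co-occurrence and hierarchy, or class imbalance structure of curated
databases.  Tests passing on this generator show the implementation learns
the planted function-to-localization structure; they do not certify
performance on real proteomes.

## Problem sizes and settings used by the shipped experiments

The package's acceptance-style experiments train on 300 synthetic proteins
(lengths 30–60, strong motifs: `k = 10`, `mu = 4`, prevalence 0.3,
`noise_rate = 0.05`), split 80/10/10, for 30 epochs with a deliberately
small model (`d_p = 32`, `h_d = 4`, 2 layers, `d_fe = 32`, `d_F = 64`,
`h_ki = 4`, pooling ratio 0.5, batch size 4, lr 3e-3 constant,
`alpha = 2`, `beta = 0.2`, `omega = 2`, weight decay 5e-4).  The auxiliary
GO tasks carry more loss weight than at full scale because, with only 240
training proteins, the function signal is what drives the shared
representation; the reconstruction weight is kept small because the
geometry target otherwise competes with the motif signal for branch
channels.  These sizes were chosen so a full training run completes in
minutes on one CPU core while leaving clear air between planted-signal
AUROC and chance.  The multi-task collaboration experiment compares median
test localization AUROC of the full model against the `no_colT` variant
over several seeds, mirroring the qualitative claim that auxiliary GO
supervision improves localization.

## Numerical choices and degenerate inputs

* Contact threshold comparisons are inclusive (`<=`).
* Softmax stabilisation by per-group max subtraction; BCE clamping 1e-7.
* Batch norm uses biased variance for both batch and running statistics; a
  single-node graph normalizes to zero (epsilon-guarded).
* Proteins shorter than a motif skip that term with a warning.
* Embedding providers must supply at least one row per residue: deficits
  are errors, surpluses (special tokens) are stripped via the provider's
  declared flank count, then truncated to the sequence length.
* Sequence/coordinate length mismatches trim to the shorter, with a
  warning, mirroring the truncation stance for embeddings.
* Single-chain structures are assumed; multi-chain files are reduced to the
  first chain with Ca atoms.
* Label vocabularies are sorted lexicographically so score columns are
  stable across runs; dataset splits floor-allocate with the remainder to
  the training partition.

## Known limitations

* Per-residue importance (the localization pooling scores) concentrates
  inside planted motif windows on some trained models but not reliably on
  every seed: the pooling layer is free to score any residues that happen
  to separate the localization classes, and nothing in the loss anchors
  its attention to the motif windows specifically.  Importance maps should
  be read as a property of one trained model, checked against external
  annotation, rather than as a guaranteed motif detector.

* The tensor backend is plain R; it is fast enough for desk-scale studies
  (hundreds of proteins, lengths <= a few hundred) but not for
  proteome-scale training.
* Fmax uses the protein-centric CAFA convention on a 0.01–0.99 threshold
  grid; the multi-label accuracy is example-based Jaccard at threshold 0.5.
  These standard forms are fixed and centralized in
  `evaluate_multilabel()` so a different convention can be swapped in.
* GO terms are flat labels; no ontology DAG propagation is performed.
* The average-precision / AUPR pair uses step-wise AP and
  monotone-interpolated AUPR per label, macro-averaged over labels with
  both classes present.
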