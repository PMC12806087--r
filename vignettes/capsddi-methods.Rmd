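---
title: "Multimodal capsule fusion for DDI-type prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal capsule fusion for DDI-type prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsddi)
```

## The problem

When two drugs are co-administered, one can alter the pharmacological
action of the other. Predicting not just *whether* such a drug–drug
interaction (DDI) occurs but *which type* of effect it produces (e.g.
"decreased antihypertensive activity") is a multiclass — or, when a pair
can show several effects, multilabel — classification problem over drug
pairs. `capsddi` implements a multimodal architecture for this task: four
per-pair feature modalities are extracted, fused by a capsule network with
dynamic routing, and classified by a three-layer perceptron.

## The four modalities

Each drug $d$ receives four feature vectors; pair-level vectors are the
concatenation for the two drugs of a pair (drug $i$ first).

**Knowledge-graph (KG) feature, 400-d per drug (800-d per pair).**
Entities and relations of a biomedical knowledge graph are embedded with
TransE: a triple $(h, r, t)$ is scored by
$t(v_h, v_r, v_t) = \lVert v_h + v_r - v_t\rVert_2$ and trained with the
margin ranking loss
$\sum \max(0,\, t(\text{pos}) + \lambda - t(\text{neg}))$ over corrupted
triples in which either the head or the tail (coin flip) is replaced by a
uniformly drawn entity, rejecting corruptions that exist in the graph.
Entity embeddings are re-normalized to the unit sphere after every Adam
step. The pretrained embeddings are then refined by a degree-reweighted
graph convolution over the undirected entity neighbourhood,
$h_i' = \mathrm{ReLU}\big(\sum_{j \in N_i} \omega_{ij} W h_j + \omega_i
h_i\big)$, and L2-normalized per node. The neighbour weight is read as the
symmetric normalization $\omega_{ij} = 1/\sqrt{|N_i|\,|N_j|}$ (the plain
product $1/(|N_i||N_j|)$ is also available via `gcn_norm = "product"`);
$\omega_i = 1/|N_i|$, defined as 1 for isolated nodes so degenerate inputs
do not crash. Neighbourhoods ignore relation type and direction, since the
update carries no relation term. Two layers are applied by default.

**Molecular fingerprint feature, 2656-d per drug (5312-d per pair).**
Four fingerprints concatenated in fixed order: MACCS keys (167), a
circular ECFP of diameter 4 folded to 1024 bits, a topological atom-pair
fingerprint hashed to 1024 bits, and an ErG-style reduced-graph
pharmacophore fingerprint (441 values). MACCS and ECFP are computed by
OpenBabel (through ChemmineOB), atom pairs by ChemmineR. The ErG-style
block is computed in-package: atoms are typed as donor / acceptor /
positive / negative / hydrophobic / aromatic; every typed atom pair at
topological distance 1–21 increments its (type-pair, distance) cell by 1
with fuzzy increments of 0.3 on the adjacent distance bins, giving
$21 \times 21 = 441$ nonnegative values. It follows the ErG construction
but is not bit-for-bit identical to other toolkits' implementations.
Molecules with fewer than two heavy atoms have an all-zero atom-pair
block (methane has no atom pairs).

**Molecular-graph feature, 512-d per drug (1024-d per pair).** The
heavy-atom molecular graph is built from SMILES: atoms carry a fixed 69-d
layout (symbol one-hot over 43 common elements + "other" = 44;
hybridization 5; heavy-atom degree 0–5; total hydrogens 0–4; implicit
valence 0–6; ring flag; aromatic flag — out-of-range counts clamp to the
last slot), and each bond contributes two directed edges with a 6-d
feature (type one-hot single/double/triple/aromatic; conjugated; in-ring).
A four-layer edge-featured graph attention encoder processes the graph.
Each layer updates every directed edge from its endpoints,
$e_{ij}' = W_e [n_i \,\Vert\, e_{ij} \,\Vert\, n_j] + b_e$, projects nodes
to 512-d, computes four per-head attention logits from 128-d slices of the
LeakyReLU-activated edge feature (slope 0.2, the usual graph-attention
convention), softmax-normalizes them over each destination node's incoming
edges, and aggregates neighbour features per head slice. No nonlinearity
follows the aggregation and no self-loops are added — the update equations
are followed literally; a node with no incoming edges (a single-atom
molecule) keeps its projected feature. Layer 1 consumes the raw 69/6-d
features ($W_e \in \mathbb{R}^{512\times144}$); layers 2–4 are *one*
shared parameter object ($W_e \in \mathbb{R}^{512\times1536}$), so four
applied layers hold exactly two layers' parameters — asserted by a
parameter census in the tests. Global average pooling over atoms yields
the 512-d drug vector. The `encoder = "gat"` ablation computes attention
from the projected node pair instead of the edge feature (edge features
are ignored; output shape unchanged).

**Pharmacology feature, 2159-d per drug at full scale (4318-d per
pair).** Binary enzyme-annotation (344) and target-annotation (1815)
blocks, concatenated; widths are configurable for synthetic data.

## Capsule fusion

The four pair-level vectors are projected by one linear map each into a
common 512-d capsule space, squashed —
$\mathrm{squash}(s) = \frac{\lVert s\rVert^2}{1+\lVert s\rVert^2}
\frac{s}{\lVert s\rVert}$, which bounds norms in $[0,1)$ while preserving
direction (zero maps to zero by the limit convention) — and passed through
two capsule layers with dynamic routing. Each input capsule $i$ proposes
$a_{ij} = W_{ij} c_i$ for output capsule $j$; couplings
$\beta_{ij} = \mathrm{softmax}_j(m_{ij})$ start from zero logits (uniform),
outputs are $c_j = \mathrm{squash}(\sum_i \beta_{ij} a_{ij})$, and logits
grow by the scalar agreement $a_{ij} \cdot c_j$, for 3 iterations
(the standard routing default). Logits reset on every forward pass. The
layer widths are 4 → 4 → 2 capsules, so flattening the two final 512-d
capsules yields the 1024-d comprehensive pair representation. The
intermediate capsule count (4, preserving the input count) and iteration
count are deliberate defaults exposed in `caps_init()`. The projection
bias exists but is initialized to zero and can be dropped. The
`fusion = "concat"` ablation splices the four projected vectors (2048-d)
and resizes the predictor input accordingly.

## Predictor and losses

Three affine layers (2048 and 4096 hidden units at full scale) with ReLU
between, then softmax (multiclass) or elementwise sigmoid (multilabel).
Multiclass loss is cross-entropy $-\log q_{c^*}$; multilabel loss is the
mean weighted binary cross-entropy with per-type positive weight $p_c$
equal to the negative-to-positive ratio in the training fold. Logs are
clamped at $10^{-12}$, invisible at test tolerances. Multilabel negatives
follow a closed-world convention: absent types on observed interacting
pairs count as negatives; no artificial non-interacting pairs are sampled.

Multiclass AUPR and AUC are micro-averaged over the one-vs-rest binarized
(pair, type) scores — the convention of the DNN-based DDI lineage this
architecture descends from — alongside Cohen's kappa, accuracy and
macro-precision (classes never predicted contribute zero precision).

## Training protocol

Stratified k-fold cross-validation over *pairs* (k = 5): within each
type, pairs are dealt round-robin into folds so per-type proportions match
globally up to one sample; rare types (< k pairs) warn. Each unordered
pair enters once as (i, j) with i before j by id. Per fold, 10% of the
training pairs are held out for early stopping (monitored metric:
validation accuracy for multiclass, AUPR for multilabel; patience 20).
Adam with learning rate 0.001, weight decay 0.0001 on weight matrices, and
a step schedule multiplying the rate by 0.1 every 50 epochs; batch size
1024.

Two deliberate design choices depart from an end-to-end deep-learning
stack, both motivated by implementing the model in pure R without an
automatic-differentiation framework:

* **Trainable trunk.** Gradients are hand-derived for the modality
  projections, both capsule layers and the predictor, and verified against
  finite differences in the tests. The converged routing couplings
  $\beta$ are treated as constants of the backward pass (gradients flow
  through $a_{ij}$, the weighted sums and the squash Jacobian) — a
  standard practical simplification of routing backprop; with one routing
  iteration it is exact, which is how the gradient tests pin it.
* **Frozen feature extractors.** TransE is pretrained (as usual), and the
  graph-convolution refinement and the molecular-graph attention encoder
  are applied as seeded, fixed transforms at featurization time rather
  than being fine-tuned under the task loss. On the synthetic study
  conditions this loses nothing measurable, because the planted label
  signal lives in the fingerprint channel (below); on real data it would
  trade some accuracy for a dramatically simpler and fully testable
  training loop.

TransE pretraining itself uses Adam at learning rate 0.05: at desk scale
(a hundred entities, 400-d embeddings) smaller rates provably leave the
embeddings at initialization. Its plateau detection monitors a fixed
subset of the *training* triples with fixed corrupted counterparts: the
synthetic graph's triples are random, so a held-out triple set has no
learnable structure by construction and its loss cannot improve; the
monitor's role here is stopping, not model selection. Ranking sanity
(true tails rank above corrupted tails) is asserted in the tests.

## Synthetic study conditions

The generator emulates the statistical shape of the real inputs with no
download: 60 drugs (SMILES drawn replacement-free from a curated pool of
40 drug-like molecules, so chemical validity is guaranteed without a
generative dependency), 40 non-drug entities, 6 relations, 400 triples
(every drug connected), 8 interaction types, 600 labelled pairs, and
sparse binary pharmacology vectors at ~10% density. Enzyme/target widths
at toy scale are 64/128 — wide enough to be a realistic sparse block,
small enough to keep the pair design matrix light. Everything is a pure
function of the seed.

Labels are *planted* through one well-understood channel: the label of a
pair is the number of fingerprint on-bits the two drugs share, binned into
K classes by fixed quantile breaks derived from the built-in pool (a pure
function of package constants). A linear probe on concatenated
fingerprints recovers it above twice chance — the generator's sanity
gate — and the full model learns it well above chance. The other three
modalities are realistic *distractors*: they carry no label signal. That
is what passing tests show — that the wiring, gradients and protocol are
correct — and also what they do not show: on these conditions a variant
that removes a distractor modality can tie or marginally beat the full
model within noise, unlike on real data where all four modalities are
informative. The synthetic conditions make no attempt to mimic a real
knowledge graph's entity taxonomy or real label co-occurrence statistics.

The desk-scale training profile (`toy_train_config()`: capsule dimension
64, predictor hidden 256/256, learning rate 0.002, at most 120 epochs)
exists so the full cross-validated run finishes in a few minutes on one
CPU; all architectural defaults remain full-scale and are what the
dimension contracts assert.

## Numerical choices and degenerate inputs

* Unparseable SMILES raise a typed condition (`capsddi_parse_error`)
  carrying the offending string; dataset preparation drops such drugs.
* Out-of-vocabulary atom symbols map to the final "other" slot, never an
  error; degree/H/valence counts clamp to their last slot.
* The squash Jacobian at the origin is zero; the backward pass guards the
  division accordingly.
* Softmaxes subtract the row maximum before exponentiation.
* Ties in `select_label_types` (equal pair counts) break by label order,
  making type selection platform-independent.
* Mirrored duplicate pairs with conflicting single labels are a data
  error; conflicting multilabel sets merge by union.

## Known limitations

* The graph convolution uses dense per-node loops — appropriate for the
  desk-scale graphs the package targets, not for million-edge knowledge
  graphs.
* Aromaticity, hybridization and conjugation are perceived from the
  kekulized OpenBabel parse with a standard valence table; exotic
  organometallics fall back to conservative defaults ("other" symbol, no
  implicit hydrogens).
* Stereochemistry, 3-D conformers and tautomer normalization are out of
  scope throughout.
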