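# capsddi

Multiclass and multilabel prediction of drug–drug interaction (DDI) types
from multimodal drug-pair features, fused by a capsule network with dynamic
routing.

When two drugs are co-administered, one may alter the pharmacological
action of the other — reducing efficacy or causing adverse reactions.
Predicting the *type* of interaction for a candidate pair, before any
clinical observation, is a multiclass (one type per pair) or multilabel
(several types per pair) classification problem. `capsddi` is aimed at
computational drug-safety researchers who want a fully reproducible,
desk-scale implementation of a multimodal architecture for this task, with
every stage testable against a seeded synthetic data generator — no
external downloads required.

## The model

Each drug *d* contributes four feature vectors, concatenated per pair
(s<sup>KG</sup> 800-d, s<sup>FP</sup> 5312-d, s<sup>MG</sup> 1024-d,
s<sup>PH</sup> 4318-d at full scale):

* **Knowledge graph** — TransE embeddings trained with the margin ranking
  loss ∑ max(0, ‖v<sub>h</sub>+v<sub>r</sub>−v<sub>t</sub>‖ + λ −
  ‖v<sub>h′</sub>+v<sub>r</sub>−v<sub>t′</sub>‖) over corrupted triples,
  refined by a degree-reweighted graph convolution
  h<sub>i</sub>′ = ReLU(∑<sub>j∈N<sub>i</sub></sub> ω<sub>ij</sub> W
  h<sub>j</sub> + ω<sub>i</sub> h<sub>i</sub>) with
  ω<sub>ij</sub> = 1/√(|N<sub>i</sub>||N<sub>j</sub>|), then L2-normalized
  (400-d per drug).
* **Molecular fingerprints** — MACCS (167) ‖ ECFP, diameter 4, 1024 bits ‖
  atom-pair, 1024 bits ‖ ErG-style reduced-graph pharmacophore (441)
  = 2656-d per drug, from SMILES.
* **Molecular graph** — heavy-atom graph with 69-d atom and 6-d bond
  features, encoded by a four-layer edge-featured graph attention network
  (4 heads × 128-d slices; attention logits computed from updated *edge*
  features; layers 2–4 share one parameter object), globally average-pooled
  to 512-d per drug.
* **Pharmacology** — binary enzyme (344) and target (1815) annotation
  blocks, 2159-d per drug.

The four pair vectors are projected to a 512-d capsule space, squashed
(squash(s) = ‖s‖²/(1+‖s‖²) · s/‖s‖), and routed through two capsule layers
(4 → 4 → 2, 3 routing iterations with couplings
β<sub>ij</sub> = softmax<sub>j</sub>(m<sub>ij</sub>) updated by dot-product
agreement); the two final capsules flatten to the 1024-d pair
representation S. A three-layer perceptron (2048, 4096 hidden units) with
softmax or sigmoid output yields per-type probabilities; training uses
cross-entropy or positively-reweighted binary cross-entropy under
stratified 5-fold cross-validation with Adam, a step learning-rate schedule
and early stopping. Ablation switches drop any modality, swap the encoder
to plain node-pair attention, or replace capsule fusion by concatenation.

## Worked example

```r
library(capsddi)

ds  <- generate_synthetic_dataset(synth_config(seed = 0))
ds$ddi
#> <ddi_table> 600 pairs, 8 types

fp <- compute_fingerprints(ds$drugs$smiles[1])
length(fp$values)
#> [1] 2656

fit <- train_model(ds, toy_train_config(seed = 0))
fit
#> <ddi_fit> multiclass task, 5 fold(s), modalities: kg+fp+mg+ph
#>           metric      mean         sd
#>             aupr 0.4301164 0.04926964
#>              auc 0.8473909 0.02452831
#>            kappa 0.3233294 0.02976415
#>         accuracy 0.4100000 0.02595402
#>  macro_precision 0.3910062 0.02933341
```

The synthetic task plants its labels through the fingerprint channel
(shared on-bit counts binned into 8 types), so chance accuracy is 0.125;
the cross-validated accuracy of 0.41 shows the full pipeline learning the
planted signal at more than three times chance, and AUC 0.85 shows the
ranking is far from random. A command-line front end over the same
functions ships in `inst/cli/capsddi`
(`capsddi simulate|prep|featurize|embed-kg|train|evaluate`).

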