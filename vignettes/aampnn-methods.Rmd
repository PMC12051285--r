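---
title: "Atom-attention message passing with contrastive pretraining: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atom-attention message passing with contrastive pretraining: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`aampnn` predicts binary molecular permeability (blood-brain barrier,
Caco-2) from SMILES with a directed message-passing neural network
(D-MPNN) whose readout is a multi-head scaled dot-product attention
layer over atoms.

A molecule is a directed graph: every chemical bond contributes two
directed bonds $v{\to}w$ and $w{\to}v$. With one-hot atom features
$x_v$ and bond features $e_{vw}$, the encoder computes

$$h^0_{vw} = \mathrm{ReLU}\!\big(W_i\,[x_v \,\|\, e_{vw}]\big)$$

and then iterates, for $t = 1 \dots T$,

$$m^t_{vw} = \sum_{k \in N(v)} h^{t-1}_{kv} - h^{t-1}_{wv},
\qquad
h^t_{vw} = \mathrm{ReLU}\!\big(h^0_{vw} + W_h\, m^t_{vw}\big).$$

Subtracting the reverse bond's state keeps a message from echoing
straight back along the bond it arrived on — the defining trick of the
directed formulation. A terminal atom's only incoming state *is* the
reverse bond, so its outgoing bond state is a fixed point of the
update; the unit tests pin this down exactly.

After $T$ steps, per-atom messages are
$m_v = \mathrm{ReLU}(W_0\,[x_v \,\|\, \sum_{w \in N(v)} h^T_{vw}])$,
stacked into $H_a \in \mathbb{R}^{M \times d}$. Each attention head
computes $\mathrm{softmax}(QK^\top/\sqrt{d_h})\,V$ with
$Q = H_aW_Q$, $K = H_aW_K$, $V = H_aW_V$ and per-head width
$d_h = d/\text{heads}$; heads are concatenated, mapped through $W_o$,
and the residual $m_v$ is added *after* $W_o$. The molecule vector is
the sum $h = \sum_v h_v$, making the representation exactly invariant
to atom reordering (a tested property). For classification, $h$ is
concatenated with the molecule's ECFP bit vector (optionally disabled —
the fingerprint-free ablation) and passed through a two- or three-layer
feed-forward head with a sigmoid output; training minimizes binary
cross-entropy with Adam.

All of the forward pass, the analytic backward pass and Adam are
implemented in base-R matrix code; there is no deep-learning framework
underneath. The backward pass is verified against central-difference
numerical gradients in the test suite, and the full forward pass
against an index-free brute-force oracle.

## Defaults and why

| parameter | default | notes |
|---|---|---|
| hidden dim $d$ | 300 | common D-MPNN practice; any multiple of the head count works, tests use 8-64 for speed |
| message steps $T$ | 3 | tuning grid spans 2-6 |
| attention heads | 4 | must divide $d$ |
| dropout | 0.0 | grid 0-0.4 in 0.05 steps; applied to atom messages and FFN hidden layers |
| learning rate | 1e-3 | Adam, grid $[10^{-4}, 10^{-3}]$ (log-uniform in the tuner) |
| FFN layers | 2 | grid \{2, 3\} |
| ECFP | radius 2, 2048 bits | configurable; folded from OpenBabel's 4096-bit ECFP by modular OR |
| classification threshold | 0.5 | probability at or above the threshold is the permeable class |

Empty neighbour sums (isolated atoms, methane) are the zero vector.
Within the attention block we apply dropout only — no layer
normalization — and attention never crosses molecule boundaries
(molecules are encoded one at a time, so no padding mask is needed).

# Contrastive pretraining

Self-supervised pretraining builds, for each molecule in a batch of
$N$, a positive view by *atom masking*: $\max(1,
\lfloor 0.25\,M \rfloor)$ uniformly drawn atoms have their feature rows
replaced by a mask token. The token is an all-zero vector with a
dedicated indicator column set to 1 — the indicator is part of the atom
schema and is zero for every real atom, so the token can never collide
with a valid encoding. Bond features are untouched.

Both views are encoded and passed through a two-layer MLP projection
head; pairs are scored by cosine similarity and trained with the
NT-Xent loss

$$\mathcal{L}_i = -\log
\frac{e^{\,\mathrm{sim}(z_i, z_i')/\tau}}
{\sum_{j=1}^{N}\big(e^{\,\mathrm{sim}(z_i, z_j')/\tau}
 + e^{\,\mathrm{sim}(z_i', z_j)/\tau}\big)},$$

averaged over the batch. The denominator is implemented exactly as
written: the positive pair is included and there are no
within-view negatives. This differs from the more common SimCLR
variant (which excludes the anchor's self-term and includes within-view
negatives); the printed form forces two analytic limits that the tests
assert — $\mathcal{L} = \log 2$ at $N = 1$ for any embeddings, and
$\log 4$ at $N = 2$ with all four embeddings identical. Temperature
defaults to $\tau = 0.1$. The corpus is split 90:10 into
train/validation; the final incomplete batch of each epoch is dropped
because contrastive losses are batch-size sensitive. Only the encoder
parameters survive pretraining — the projection head is discarded — and
they are transferred as initialization for fine-tuning (fully
fine-tuned by default; `freeze_encoder = TRUE` keeps them fixed).

# Data handling

**Splits.** 85% train / 15% test, with the training portion divided so
that calibration and validation are 70% and 15% *of the full dataset* —
the "70:15" ratio is read as fractions of the whole, which is the only
reading consistent with 85 = 70 + 15. Splitting is random and
stratified by class within one sample (largest-remainder
apportionment); scaffold-holdout evaluation can be emulated by
splitting on `murcko_scaffold_stats()` output. Cross-validation uses
stratified folds and reports mean and sample standard deviation per
metric.

**Caco-2 curation.** Records pass through: parse, keep the largest
organic fragment (salt/solvent stripping), OpenBabel charge
neutralization and canonicalization, retention of logPapp in
$[-8, -3.5]$ (log10 cm/s), then two-cluster k-means on the retained
logPapp values (`stats::kmeans`, k = 2, 10 restarts, seeded). One-
dimensional two-cluster k-means induces a cut point, so labels are
monotone in logPapp; the reported threshold is the midpoint between
the maximum of the lower cluster and the minimum of the upper cluster.
The package reports its own derived threshold rather than asserting any
particular value. Full ChEMBL-style standardization is out of scope;
the applied steps are exactly those listed.

**Metrics.** ROC-AUC is computed by the rank (Mann-Whitney) formula —
the probability that a random positive outranks a random negative with
ties counted one half — and is tested against an $O(n^2)$ pairwise
oracle and against `pROC`. Accuracy, precision, sensitivity and
specificity come from the confusion matrix at the 0.5 threshold;
precision is `NA` when nothing is predicted positive.

**Hyperparameter search.** `bayes_optimize()` is a compact
tree-structured Parzen estimator over the published grid (message steps
2-6, batch 128/256/512, dropout 0-0.4 step 0.05, 2-3 FFN layers,
log-uniform learning rate $10^{-4}$-$10^{-3}$): after a random warm-up,
trials are split at the 70th score percentile, candidates are sampled
from the good-set density per parameter, and the candidate maximizing
the Parzen density ratio is evaluated. Defaults are 20 iterations of 20
epochs each.

# Featurization conventions

The atom schema is a documented convention in the widely used D-MPNN
style: atomic number (1-100 + unknown bucket), heavy-atom degree (0-5 +
unknown), formal charge (-2..+2 + unknown), chirality tag
(none/CW/CCW/either), bonded-hydrogen count (0-4 + unknown),
hybridization (SP/SP2/SP3/SP3D/SP3D2 + unknown), plus the mask
indicator column — 131 columns in total. Bonds encode type
(single/double/triple/aromatic), an in-ring flag and stereo annotation
(none/up/down/either), 9 columns.

Parsing is delegated to OpenBabel (via ChemmineOB) with hydrogens made
explicit so that bonded-H counts are exact, then folded back into the
H-count feature; ring perception and aromaticity come from ChemmineR's
ring finder on the same molblock. Hybridization is rule-based from the
parsed bond orders: a triple bond or two doubles gives SP, one double
or an aromatic flag gives SP2, five or six connections give SP3D or
SP3D2, everything else SP3. Chirality is read from the molblock parity
field when the toolkit emits it and falls back to "none" — stereo
information in SMILES written without coordinates frequently does not
survive the conversion, which is the main known gap of this
featurization. Charged species are kept as parsed.

# The synthetic fixture generator

`generate_fixture()` assembles molecules from a curated fragment
grammar: eleven ring cores (seven without an aromatic nitrogen, four
with one) with an optional substitution site, and twenty common
medicinal-chemistry substituents. Every string is valid by
construction, and the tests assert 100% parseability.

* *Classification task*: the label marks the presence of the planted
  substructure — by default an aromatic nitrogen, carried entirely by
  the core choice, so noiseless labels are perfectly recoverable by
  substructure matching. Optional label noise flips labels
  independently.
* *Permeability task*: logPapp is drawn from a two-component Gaussian
  mixture with modes $-6.5$ and $-4.5$ (log10 cm/s), standard
  deviation 0.3 and equal weights — the bimodal shape that makes
  two-cluster k-means labeling meaningful. The value is independent of
  the structure.

What the generator does *not* emulate: the scaffold diversity, size
distribution and label imbalance of real permeability datasets, the
correlation between structure and permeability, assay noise, or
stereochemistry-dependent effects. Passing tests on this fixture
establish that the machinery is correct — graph construction, gradient
flow, loss descent, reproducibility — not that the model generalizes to
real Caco-2 or BBB data, which would require the original curated
datasets and full-scale pretraining.

# Numerical choices

* Glorot-uniform initialization for all weight matrices; FFN biases at
  zero. Adam with $\beta_1 = 0.9$, $\beta_2 = 0.999$,
  $\epsilon = 10^{-8}$.
* Softmax rows are max-shifted before exponentiation; BCE probabilities
  are clamped to $[10^{-12}, 1-10^{-12}]$.
* Every stochastic step (splits, shuffling, masking, dropout,
  initialization, the TPE search) draws from an explicitly seeded
  stream derived from the user-facing seed, so training histories are
  bit-identical across runs with the same seed.
* Cosine similarity errors on zero vectors rather than returning a
  conventional value.
* Checkpoints are RDS containers tagged `aampnn_checkpoint`, version 1,
  holding either a pretrained-encoder payload or a full model; loading
  validates both tags.

# Interpretation

Per-atom attention weight is the mean over heads of the attention an
atom *receives* (column means of the row-stochastic head matrices),
renormalized to sum to one per molecule; `head_aggregation = "max"` is
available. Because softmax weights are nonnegative they cannot encode a
direction of effect, so the signed per-atom contribution is defined by
single-atom occlusion: the drop in predicted permeability when that
atom's features are replaced by the pretraining mask token. This
occlusion definition is this package's own interpretation choice, not a
published derivation. Heatmaps color positive contributions green and
negative red with opacity proportional to magnitude, and every export
also writes a fixed-format per-atom CSV so repeated exports are
byte-identical.

`embedding_map()` reduces molecule vectors to two dimensions with PCA
(`stats::prcomp`), which is deterministic and adequate for the
pretrained-versus-scratch separation checks in the tests; a
neighbourhood-preserving embedding such as t-SNE would need an
additional dependency and offers no benefit at fixture scale.

# Problem sizes

The test suite runs the encoder oracle on all small (at most six heavy
atoms) fixture molecules, permutation invariance on 200 fixture
molecules with five reorderings each, learning sanity on a 500-molecule
planted-substructure task (held-out ROC-AUC checked against 0.9), a
200-molecule/3-epoch pretraining descent check, curation on a
400-record bimodal sample, and the full CLI pipeline on a 160-molecule
dataset. `scripts/acceptance.R` recomputes the same quantities from
scratch at those sizes. Hidden dimensions of 8-64 are used throughout
the tests; the defaults (d = 300) remain the recommendation for real
data.

# Known limitations

* Stereochemistry mostly collapses to the "none" category (see above).
* Aromaticity and hybridization are toolkit/rule conventions and can
  disagree with other software on exotic ring systems.
* The Murcko scaffold keeps ring systems and linkers after iterative
  terminal-atom pruning; exocyclic double-bonded atoms attached to a
  ring are pruned, which differs from implementations that retain them.
* No regression mode, no multi-task heads, no probability calibration.
* Training is single-threaded CPU code intended for datasets in the
  thousands, not hundreds of thousands, of molecules.
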