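---
title: "Scoring protein docking models with gated graph attention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein docking models with gated graph attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

*Ab initio* protein-protein docking produces thousands of candidate models
(decoys) per target, of which only a handful are near-native.  A scoring
function must rank the pool so that at least one acceptable model - in the
CAPRI sense - appears among the top few selections.  `graphdock`
implements an atom-graph scorer for this task: the interface of a
two-chain model is turned into a pair of graphs, processed by shared
gate-augmented graph attention layers, and mapped to the probability that
the decoy is of acceptable quality.

## The model

**Interface extraction.**  A residue belongs to the interface when its
minimum heavy-atom distance to any residue of the other subunit is at most
10 Å.  All heavy atoms of the selected residues become graph nodes
(receptor block first, then ligand, in file order).

**Two adjacencies.**  The covalent graph \(A^1\) has
\(A^1_{ij} = 1\) when atoms \(i\) and \(j\) are covalently bonded or
\(i = j\), and 0 otherwise.  The interaction graph \(A^2\) copies \(A^1\)
within each molecule and adds Gaussian-weighted cross-molecular edges

\[
A^2_{ij} = e^{-(d_{ij}-\mu)^2/\sigma},\qquad d_{ij}\le 10\,\text{Å},
\]

for atom pairs spanning the two molecules, with learnable scalars
\(\mu\) (init 0.0) and \(\sigma\) (init 1.0, clamped \(\ge 10^{-6}\))
shared by all cross edges.  Because \(\mu\) and \(\sigma\) are trained,
the graph object stores the cross-distance matrix and rebuilds \(A^2\)
every forward pass, so gradients reach the edge parameters.  We treat the
pair as a single global \((\mu, \sigma)\) rather than per-layer copies:
the edge model defines one interaction graph, and all layers read it.

**Node features.**  Each heavy atom carries 23 binary features:
atom-type one-hot over (C, N, O, S, H), heavy-atom degree 0-5, attached
hydrogens 0-4, implicit valence 0-5, and an aromatic flag
(5+6+5+6+1).  Chemistry comes from a versioned residue template table
(`inst/extdata/residue_*.csv`): decoys usually lack hydrogens, so
attached-H counts, valences and aromatic ring membership (His, Phe, Tyr,
Trp side chains) are template properties, never read from the file.  The
H slot of the atom-type one-hot is kept for shape compatibility but never
set, since nodes are heavy atoms only.  Non-template residues degrade to a
1.9 Å distance-bond rule with element-based typing and aromatic 0.

**Gated attention layer.**  With \(x_i' = W x_i\), attention logits are
the symmetric bilinear form
\(e_{ij} = x_i'^{\mathsf T} E x_j' + x_j'^{\mathsf T} E x_i'\), computed
only where \(A_{ij} > 0\).  The normalized coefficient is
\(a_{ij} = \operatorname{softmax}_{j \in N_i}(e_{ij})\, A_{ij}\) - note
the adjacency weight multiplies *after* normalization, so rows of a
weighted \(A^2\) need not sum to 1 (for binary \(A^1\) they do, exactly).
Aggregation is \(x_i'' = \sum_j a_{ij} x_j'\), followed by a gated
residual update \(x_i^{out} = c_i x_i + (1-c_i) x_i''\) with
\(c_i = \operatorname{logistic}(D\cdot(x_i \| x_i'') + b)\).  There is no
multi-head attention and no LeakyReLU; the attention here is bilinear and
symmetric by construction, and no extra activation is applied between
layers beyond the gate.

**Network.**  Features are embedded \(23 \to 140\) by a single affine
layer; we apply no activation there, the minimal choice for a one-layer
embedding.
Four attention layers are applied; each layer runs once against \(A^1\)
and once against \(A^2\) *with shared weights* and passes on the
difference \(x^{(2)} - x^{(1)}\), so everything the two passes agree on -
all purely intramolecular structure - cancels, and only intermolecular
signal propagates.  The node embeddings are sum-pooled into a 140-vector
and a 4-layer FC head (140, 128, 128, 128, 1; ReLU between layers,
logistic at the end) yields the probability.  Dropout 0.3 is applied in
training mode after the embedding, after each attention layer, and after
FC layers 1-3 (every layer except the last - whether the canonical design
placed dropout inside the attention block is not documented; ours sits
between blocks).

**Consequences worth knowing.**  The representation is rigid-motion
invariant (only distances and templates enter) and permutation invariant
(attention is masked per node; pooling is a sum).  If no cross-molecular
pair falls within 10 Å, \(A^2 = A^1\) and the score collapses to a
feature-independent constant - the subtraction architecture scores
*interfaces*, not chains.

## Training

Decoy pools are heavily imbalanced, so batches are class-balanced: each
batch of 32 holds 16 correct (acceptable-or-better) and 16 incorrect
decoys; an epoch is one shuffled pass over the negatives with positives
resampled with replacement (the alternative - defining an epoch over
positives - would shrink an epoch to a few batches at realistic class
ratios).  The loss is binary cross-entropy on the logistic output,
optimized by Adam at learning rate 0.002 and weight decay 0 for 100
epochs by default; fine-tuning from a checkpoint uses 0.0002 (a
second-stage 0.00002 is config-expressible).  All weights are Glorot
uniform, biases 0.  One master seed fans out to initialization, batch
shuffling and dropout, so runs are exactly reproducible on a single
thread.  Validation accuracy (probability threshold 0.5) selects the
retained checkpoint when a validation set is given; AUC is also reported.

The forward/backward pass is implemented twice: a readable R reference
(`gatLayer()` and friends) and a compiled RcppArmadillo path used by the
training loop.  The two are compared to machine precision in the tests,
and analytic gradients - including \(\partial L/\partial\mu\) and
\(\partial L/\partial\sigma\) through the softmax support - are checked
against central finite differences.

## CAPRI metrics

`capriMetrics()` computes the standard triple: **iRMSD** (Cα RMSD over
native-defined 10 Å interface residues after Kabsch superposition of that
set), **lRMSD** (ligand Cα RMSD after superposing receptors only), and
**fnat** (fraction of native cross-subunit residue contacts - any
heavy-atom pair within 5 Å - preserved in the decoy).  Correspondence is
by residue key (chain, number, insertion code); a decoy missing a native
interface residue is a hard error, while residues lacking a Cα are
dropped with a warning.  The class table is the standard CAPRI scheme:

| class | fnat | and (lRMSD or iRMSD) |
|---|---|---|
| high | ≥ 0.5 | ≤ 1.0 / ≤ 1.0 |
| medium | ≥ 0.3 | ≤ 5.0 / ≤ 2.0 |
| acceptable | ≥ 0.1 | ≤ 10.0 / ≤ 4.0 |

The cascade is the community-standard table and ships as data
(`capriThresholds()`) so alternate threshold sets are testable.
Homodimer symmetry-aware chain mapping is out of scope.

## The synthetic decoy generator

Benchmark decoy archives are large downloads; `makeDecoyDataset()`
instead builds desk-scale labeled sets that exercise every stage.  A toy
native is two poly-alanine chains (defaults: 6 + 5 residues) with
idealized backbone geometry placed in contact (≥ 3 cross-residue
contacts at 5 Å); alanine keeps the template featurizer fully applicable.
Decoys are rigid-body ligand perturbations: a decoy aims "correct" with
probability `positiveFraction` (default 0.1, mimicking realistic decoy
pools in which roughly one model in ten is acceptable), candidate
positives drawing rotations up to 12° and translations up to 0.8 Å,
candidate negatives rotations of 40-180° plus 2.5-8 Å translations
biased into the interface plane so the chains stay in contact.  Because
no closed form maps perturbation magnitude to CAPRI class, each candidate
is classified with `capriMetrics()` and redrawn (bounded retries) until
its class matches the aim; stored labels therefore always equal the class
of the recomputed metrics.  What this emulates is pose diversity with a
realistic label imbalance; what it does **not** emulate is side-chain
chemistry, clash relaxation, shape-complementary wrong poses, or the
sequence diversity of real benchmarks - so passing the synthetic learning
experiment shows the architecture can learn interface geometry, not that
it reaches benchmark-scale accuracy on real decoys.

## Numerical and design choices

* Attention logits are clipped to ±50 before exponentiation; softmax is
  max-subtracted per row.  The clip treats the bound as a hard saturation
  (zero gradient beyond it).
* Softmax support is the structural neighbourhood \(\{j: A_{ij}>0\}\)
  including the self-loop, taken from the bond/cutoff pattern rather than
  from numeric magnitude, so underflowing Gaussian weights do not drop
  neighbours.
* Node order is fixed (receptor block, then ligand, file order) purely
  for reproducible serialization; all scores are order-invariant.
* Peptide bonds to residues outside the interface selection are dropped -
  edges exist only between interface atoms.
* Alternate locations keep the first conformer; the first MODEL of
  multi-model files is used; HETATMs, waters and cofactors are skipped.
* Interface cutoff, cross-edge cutoff (both 10 Å) and contact cutoff
  (5 Å) are distinct constants even though two share a default.
* Desk-scale problem sizes: the packaged experiments use 8 targets x 60
  decoys on 6+5-residue toys (~55 interface atoms), which keeps a 30-epoch
  training run in the minutes range on one core while leaving every code
  path identical to full-scale use.

## Worked example

```{r, eval = FALSE}
library(graphdock)

ds <- makeDecoyDataset(8, 60, positiveFraction = 0.1, seed = 7)
trainRecs <- datasetRecords(ds, 1:6)
testRecs  <- datasetRecords(ds, 7:8)

fit <- trainNetwork(trainRecs, trainingConfig(epochs = 30, seed = 11))
v <- validateNetwork(testRecs, fit$network)
v$auc      # separation of correct from incorrect held-out decoys

vv <- validateNetwork(datasetRecords(ds, 7), fit$network)
ranked <- rankDecoys(vv$scores$decoyId, vv$scores$score, vv$scores$label)
hasHit(ranked, 5)   # an acceptable model in the top 5?
```

## Known limitations

* Pairwise (two-subunit) models only; multichain complexes and peptide
  docking are out of scope.
* No GPU path and no sparse-matrix engineering; interfaces of a few
  thousand atoms are fine, whole proteasomes are not.
* The scorer is as good as its training decoys; the shipped generator is
  a development and testing instrument, not a benchmark replacement.
* Hit-rate ties are broken by input order (stable sort), which is a
  convention, not a claim.
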