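---
title: "Predicting inter-chain residue distances for protein dimers: models, choices and limits"
author: "dimernet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting inter-chain residue distances for protein dimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimernet)
```

## The problem

Deep learning predicts *intra*-chain residue–residue distances of protein
monomers well; the *inter*-chain distances that determine how two chains of
a complex dock against each other are much harder, because co-evolutionary
signal between chains is sparser and the monomer structures say nothing
directly about the binding pose.  `dimernet` implements a complete,
trainable pipeline for this problem: given the tertiary structures of the
two monomers of a dimer, their sequence profiles and co-evolutionary
features derived from a (paired) multiple sequence alignment, an
attention-powered 2D residual network predicts, for every residue pair, a
probability distribution over discretized distances (a *distogram*) for two
distance definitions at once — the minimum heavy-atom distance and the
Cb–Cb distance.

The package covers the whole path at desk scale: format I/O (PDB, A3M,
PSI-BLAST PSSM, CASP-RR contact lists), feature assembly, the network and
its training loop, inference post-processing, the standard contact
evaluation metrics, and a synthetic-data generator that makes every stage
testable without external databases or GPU-scale training.

## Input features

For a homodimer of monomer length $L$ the network input is an
$L \times L \times 186$ tensor; for a heterodimer the side is $L_1 + L_2$.
The channel order is fixed and recorded in each `FeatureStack`:

1. **Intra-chain distance channel (1)** — Cb–Cb distances of the monomer(s)
   in Angstrom (Ca substitutes for glycine).  For heterodimers the two
   monomer maps occupy the diagonal blocks and the inter-chain blocks are
   zero: the network receives each chain's internal geometry but never the
   answer.  Distances are passed raw, unbinned and unnormalized;
   normalization is the network's job (see RCIN below).
2. **Coupling-score channel (1)** — a CCMpred-style pseudo-likelihood
   coupling matrix computed from the dimer MSA by external tools and
   ingested from a tensor archive (or synthesized).
3. **Row-attention channels (144)** — MSA-transformer-style attention maps,
   ingested as-is.  We deliberately do not symmetrize or rescale them; the
   maps are used raw, and whether clipping would help is left to the
   network's input convolution.
4. **Tiled PSSM channels (40)** — the $L \times 20$ log-odds profile
   (vertically concatenated across chains for heterodimers) is
   cross-concatenated element by element: cell $(i, j)$ carries
   $(\mathrm{row}_i, \mathrm{row}_j)$.

Heterodimer MSAs are built by pairing the two monomer alignments by
organism: for each organism present on both sides, the row with the highest
sequence identity to the query is taken from each MSA and the two rows are
concatenated.  The package exposes this as two entry points
(`pairByTaxonomy()`, `pairByTopIdentity()`, mirroring the training-time and
test-time procedures of the original pipelines they follow); as specified
here — one argmax-identity row per shared species — the two procedures
compute the same selection and differ only in provenance labelling.
Sequence identity is computed over the query's columns with gaps counted as
mismatches, and ties broken by earlier row order, so pairing is
deterministic.  Alignment depth is summarized by `computeNeff()` with the
community-standard 80% identity clustering threshold.

## Network architecture

The input tensor passes through a 2D convolution and a **Maxout** reduction
(group size 2), then a trunk of residual blocks, then two softmax heads.
Each block applies, in order: RCIN normalization → 3×3 convolution → ELU →
3×3 convolution → squeeze-and-excitation (SE) channel attention → spatial
attention → residual addition.  The SE-before-spatial order is part of the
design; the remaining intra-block order is our choice, documented here
because alternatives (e.g. post-activation) were genuinely open.

**RCIN** runs three standardization branches in parallel — per-row, per
column, and per-channel over the whole map, each with a learnable
channel-wise affine — concatenates them and fuses back to the trunk width
with a 1×1 convolution.  The fusion is our resolution of an underdetermined
design: concatenation + 1×1 convolution keeps the residual addition
shape-valid and lets the network weight the three normalizations.  All
standardizations use $\varepsilon = 10^{-6}$ inside the square root; a
constant map therefore standardizes to zero rather than dividing by zero,
and $1 \times 1$ maps pass through as their affine bias.

**SE attention** gates each channel by a sigmoid bottleneck (reduction 16
by default) applied to the spatial mean of that channel; **spatial
attention** gates each position by a sigmoid of a 3×3 convolution over the
channel-mean and channel-max pooled maps.  Maxout group size 2 and SE
reduction 16 are conventional defaults; trunk kernels are 3×3 and the
activation is ELU throughout.

**Layer counting.** The published architecture constant is 156 convolution
layers of 64 filters.  The package counts: 1 input convolution + 76 blocks
× 2 trunk convolutions + 1 shared pre-head convolution + 2 head
convolutions = 156.  Auxiliary 1×1 RCIN fusions, SE bottleneck layers and
the spatial-attention convolution are excluded from the tally.  This
counting rule is a declared convention (`networkSummary()` lists exactly
which layers are counted); anyone comparing parameter counts against other
implementations should check it first.

```{r arch}
net <- buildNetwork(networkConfig())   # 156 conv layers, 64 filters
networkSummary(net)$convLayers
```

**Output.**  Both heads classify each cell into 42 distance bins: bin 0 is
$[0, 2)$ Å, bins 1–40 tile $[2, 22)$ Å in half-open 0.5 Å steps, bin 41 is
$[22, \infty)$.  A distance of exactly 22 Å falls in bin 41 (the bins are
half-open; the boundary choice is ours and is pinned by tests).  One head
is trained against minimum heavy-atom distances, the other against Cb–Cb
distances — the only consistent reading of a dual-head design whose two
targets are named but not assigned per head.

## Training

Only inter-chain cells carry loss: for heterodimers the mask covers the two
off-diagonal blocks ($2 L_1 L_2$ cells), for homodimers every cell of the
$L \times L$ map is an inter-chain pair, so the mask is full.  The loss is
the masked mean cross-entropy of each head, summed with equal weight (the
relative weighting is unstated in the lineage; equal weight is the neutral
choice).  The schedule is two-phase: Adam at $10^{-3}$ for 30 epochs, then
plain SGD starting at $10^{-4}$ with a tenfold cut every 20 epochs for 50
more.  Batch size is 1, which sidesteps padding for variable-size inputs.
`trainLoop()` checkpoints per epoch when asked and aborts on a non-finite
loss; checkpoint selection against a validation set is left to the caller.

Every gradient in the hand-derived backward pass (convolutions via
im2col/GEMM in compiled code, Maxout routing, all three RCIN branches, the
fusion, SE, spatial attention, the softmax/cross-entropy heads) is verified
against central finite differences in the test suite.

## Inference

* **Ensemble averaging** (`averageEnsemble()`): distograms predicted from
  different MSAs are averaged per cell; a mean of distributions is a
  distribution.
* **Two-order averaging** (`averageTwoOrders()`): a heterodimer is
  presented in both chain orders; the inter-chain block of the BA
  prediction is transposed onto the AB orientation and averaged with it.
* **Contact conversion** (`contactMap()`): the probability that the
  distance is below 8 Å is the mass of bins 0–12 (8 Å is exactly a bin
  boundary).  For other thresholds the straddling bin contributes a linear
  fraction.  Conversion uses the heavy-atom head, because the 8 Å contact
  definition is a minimum-heavy-atom definition; the Cb head is exposed for
  downstream modelling.
* **Ranking** (`rankContacts()`): descending probability, ties broken
  lexicographically.  For homodimers a contact and its mirror are one
  prediction, so symmetric deduplication (max of the two scores, $i \le j$)
  is on by default, with a flag to disable it since published evaluations
  do not state their convention; both behaviours are tested.
* **Confidence** (`confidenceScore()`): the mean probability of the top
  $\lfloor L/5 \rfloor$ predictions (minimum 1), which tracks realized
  precision.

## Evaluation metrics

`trueContacts()` applies the strict definition: a residue pair is in
contact when the minimum over all heavy-atom pairs is **less than** 8 Å
(exactly 8 is not a contact).  `evaluationReport()` produces the customary
panel: precision of the top 5, 10, $L/10$, $L/5$, $L/2$ and $L$
predictions ($L$ = monomer length, or the shorter chain for heterodimers;
floor with minimum 1), accuracy order (per-mille rank of the first correct
prediction over $L_1 + L_2$ residues; undefined and excluded from set
means when nothing is correct, with the count reported), accuracy rate
(percent of dimers with a top-10 hit) and the rank-based (Mann–Whitney)
AUC with half-credit ties.  Dimers with zero true contacts are excluded
from precision means.

## The synthetic benchmark

The generator exists so that feature assembly, the network, training,
inference and evaluation can be exercised end to end without external
databases or the published trained weights.  `generateToyDimer()` builds
two idealized helical chains (2.3 Å radius, 1.5 Å rise, 100°/residue) with
three pseudo-heavy atoms per residue — CA, CB, and an outward CG — so the
minimum-heavy-atom and Cb–Cb ground truths differ measurably and both
heads have distinct targets.  The chains are placed side by side and the
inter-axis distance is stepped down until the interface holds at least
$\min(L_1, L_2)/4$ contacts.  Two realism requirements matter:

* **The docking pose must vary.**  Helix phases and the axial offset are
  drawn from the seed; otherwise every dimer would share one interface
  location and a trained network would memorize *where* contacts live
  instead of reading the co-evolutionary channels — early versions of the
  generator without this variation reached perfect precision at every
  signal level, which is a property of the benchmark, not of the method.
* **Low signal must be genuinely uninformative.**  The planted signal is an
  *observed* contact indicator: at signal fraction `snr`, each true contact
  is visible with probability `snr` and `round((1 − snr) · n_true)`
  spurious contacts are planted, drawn once per example and shared across
  the coupling channel and the first 8 attention channels, then mixed as
  `snr · signal + (1 − snr) · noise`.  Sharing the corruption across
  channels means channel averaging cannot recover hidden contacts — a
  naive per-channel mixture is separable at any `snr` once several signal
  channels are averaged.  This emulates the shallow-MSA regime, where
  co-evolution both misses true couplings and reports spurious ones.  At
  `snr = 1` true contacts are perfectly separable (AUC 1); at `snr = 0`
  the channels are uncorrelated with the truth.

Confining signal to the coupling channel plus 8 of 144 attention channels
gives the SE channel attention a real selection task; the PSSM channels are
pure noise by design.

What the synthetic benchmark does **not** emulate: real protein geometry
(side-chain packing, sheet interfaces, shape complementarity), the
phylogenetic correlation structure of real MSAs, or realistic channel
statistics of CCMpred/MSA-transformer outputs.  Passing the synthetic
tests therefore demonstrates that the machinery — features, network,
masked loss, optimization, inference averaging, metrics — is implemented
correctly and can extract planted inter-chain signal; it says nothing
about accuracy on real complexes, which depends on the published training
data and weights that are outside this package's scope.

## The desk-scale experiments

The acceptance experiments (in `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) use problem sizes chosen to keep a full run in
minutes on one CPU while leaving clear statistical margins:

* **Signal recovery**: 40 heterodimers of 24+24 residues at `snr = 0.8`,
  32 for training and 8 held out; a reduced network (12 counted
  convolutions, 16 filters, SE reduction 4) trained 10 epochs with Adam at
  $10^{-3}$.  Held-out top-$L/5$ precision is compared against the exact
  random baseline, the interface density — a random ranking's expected
  precision at any depth.  The requirement is a ≥3× ratio; the trained
  network typically reaches 6–9×.
* **Confidence–precision**: the same trained model is probed on 32 fresh
  dimers whose `snr` spans 0.2–0.9.  Probing a fixed-competence model
  across input quality mirrors the real experiment (one trained model
  across targets of varying MSA depth) and isolates what the confidence
  score must do: rank targets by how much signal the input actually
  carried.  The Spearman correlation between `confidenceScore()` and
  realized top-$L/5$ precision is required to be positive (> 0.3) and
  lands around 0.7–0.9 under these conditions.

Training twice (once per experiment) would double the compute for a weaker
probe: a model trained on mixed-quality examples underfits at this scale
and its precision no longer orders by input quality.

## Numerical and degenerate-input choices

* All standardizations: $\varepsilon = 10^{-6}$ inside the square root.
* Maxout ties route gradients to the first maximal channel; spatial-max
  pooling likewise.
* `discretizeDistance()` rejects negative or non-finite distances; bins are
  half-open, so boundary distances land in the upper bin.
* Altloc resolution keeps the highest-occupancy copy, first occurrence on
  ties; hydrogens are dropped by element symbol, falling back to the PDB
  atom-name convention.  Residues missing from a structure are indexed by
  structure order (SEQRES gaps are not re-inserted) — the distance map and
  MSA are assumed to be on the same residue ordering.
* Organism tags accept UniProt `OX=` taxonomy IDs or a trailing bracketed
  binomial; rows with neither simply never pair.
* `L/k` list sizes use floor with a minimum of 1 everywhere.

## Limitations

The package trains and evaluates at desk scale; it does not ship trained
weights, does not run the external MSA/co-evolution tools (their outputs
are ingested), and does not reconstruct 3D complexes from predicted
distances.  Published benchmark accuracies on CASP/CAPRI-derived sets
require the original training corpus and weights and are not reproducible
from this package alone.
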