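---
title: "Methods: stacking-ensemble LRI prediction and three-point CCC scoring"
author: "stackCCC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacking-ensemble LRI prediction and three-point CCC scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

Cell–cell communication (CCC) between cell types is largely mediated by
ligand–receptor interactions (LRIs).  Curated LRI catalogues are small,
so CCC analyses that rely only on known pairs miss signalling routes.
`stackCCC` addresses this in two stages:

1. **LRI prediction.**  Protein sequences are encoded into fixed-width
   descriptor vectors, reduced by PCA, and concatenated into
   ligand|receptor pair vectors.  Negative training pairs are
   constructed from unlabeled candidates by a centroid-distance rule,
   and a stacking ensemble — a polynomial-kernel SVM, a 1D convolutional
   network and a multi-head attention classifier feeding a softmax
   meta-perceptron — emits an interaction probability per candidate
   pair.
2. **CCC scoring.**  Interactions passing a probability threshold and
   an expression filter are converted into sender-to-receiver strengths
   between annotated cell types using three expression-based scores,
   combined by the PERT three-point estimate.

This vignette records the model, its assumptions, the tunable
parameters, and the numerical and design choices that were genuinely
open.

# Sequence encoding

Each protein is described by four descriptor families over the 20
canonical residues (non-canonical letters such as `X`, `B`, `U` are
stripped with a warning rather than rejected, because curated sequence
databases contain them occasionally):

* **AAC** (20): residue frequencies, fixed alphabetical order.
* **CKSAAP** (2400): for each gap $k \in \{0,\dots,5\}$, the 400
  ordered residue pairs separated by $k$ intervening residues, scored
  $\mathrm{count}/(L-k-1)$.  The denominator is the number of valid
  gapped pairs, so every gap block is a probability distribution —
  this keeps blocks comparable across sequence lengths.
* **CTD** (273): 13 physicochemical properties, each partitioning the
  residues into 3 groups; group fractions (composition, 39), adjacent
  inter-group transition fractions (39), and the percent positions of
  the first and the 25/50/75/100% occurrence landmarks per group
  (distribution, 195).  The landmark index is
  $\max(1, \lceil q\,n_g \rceil)$; an absent group contributes five
  zeros.  The group tables ship in the package source with a version
  tag (`ctd-groups-v1`).
* **Conjoint triad** (343): residues mapped to the standard 7 classes
  (by dipole and side-chain volume), all $7^3$ consecutive class
  triples scored $\mathrm{count}/(L-2)$.

The concatenation AAC | CKSAAP | CTD | CTriad is 3036-dimensional.  The
encoders are vectorized but are verified in the test suite against
naive brute-force enumerators written independently of the
implementation.

## Dimension reduction

A single PCA (centred, unscaled, via SVD) is fitted on the **union** of
all ligand and receptor descriptor vectors rather than per role: a
shared latent space makes the ligand and receptor halves of a pair
vector commensurable, and nothing in the classifier distinguishes the
roles other than block order.  The retained dimension defaults to
$d = 200$ so pair vectors have width $2d = 400$, matching the
classifier input width.  Component signs are fixed (largest-magnitude
loading positive) so fits are bit-reproducible.

# Negative construction in the positive-unlabeled setting

Only interacting pairs are catalogued; negatives must be constructed
from unlabeled candidates.  Random selection risks planting hidden
positives in the negative class, so the package uses a
centroid-distance band: with $a$ the centroid of the positive pair
vectors and $\mathit{Dis}_i$ the Euclidean distances of positives to
$a$,

$$\mathit{disLen} = \mathit{maxDis} - \mathit{minDis},$$
$$\mathit{minRange} = \mathit{minDis} + (1-\mathit{pre})\cdot 0.5\cdot \mathit{disLen}, \qquad
  \mathit{maxRange} = \mathit{maxDis} - (1-\mathit{pre})\cdot 0.5\cdot \mathit{disLen}.$$

A candidate is eligible as a negative iff its distance to $a$ falls
**strictly outside** $[\mathit{minRange}, \mathit{maxRange}]$; a
distance exactly on a bound counts as inside (we read "does not fall
within" as strict exteriority).  `pre` defaults to 0.6; at `pre = 1`
the band is the full positive range, at `pre = 0` it collapses to the
midpoint, so the eligible set can only shrink as `pre` grows — a
property the test suite asserts.  The number of selected negatives
defaults to the number of positives (class balance), drawn as a seeded
uniform subsample of the eligible set, never reusing a known positive
pair identifier.

# The stacking ensemble

The labelled pairs are split 70/30 (stratified, seeded).  The 70%
"basic" part trains three base learners:

* **SVM**: soft-margin SVM with polynomial kernel
  $(\gamma\, x\cdot x' + c_0)^3$, $\gamma = 0.1$, $C = 2.5$,
  tolerance $10^{-3}$ (the values selected by grid search in the
  method's development).  Class probabilities come from a Platt-style
  logistic calibration fitted in-package on the decision values; this
  keeps the whole pipeline deterministic for a fixed seed, which an
  internal cross-validated calibration would not.
* **1D-CNN**: the 400-wide pair vector as a 1-channel signal through
  three blocks of conv(3×1, stride 1, zero-padded) → batch-norm → ReLU
  → max-pool(2×1, stride 2) with 32/64/128 filters, then fc(128, ReLU)
  → fc(2).  Zero padding keeps the length arithmetic exact
  ($400 \to 200 \to 100 \to 50$), so the first dense layer sees
  $128 \times 50$ features; any input of width ≥ 8 survives the three
  halvings.  Trained 30 epochs, batch 64, Adam at $10^{-3}$ with
  weight decay $10^{-5}$.
* **MHA**: batch normalization, then multi-head attention with 8 heads
  of width $400/8 = 50$, output projection, fc(256, ReLU), 20%
  dropout, fc(2).  A flat pair vector has no natural token axis; we
  treat each sample as a **single token** of width 400, which matches
  every stated dimension.  With one token the softmax attention weight
  is identically 1, so the attention reduces to the value/output
  projections — the general scaled-dot-product operator is still
  exposed and tested separately as `scaledDotAttention()`.

Batch-norm layers keep running mean/variance estimates (momentum 0.9)
and use them at inference, so predictions do not depend on batch
composition.

Each trained learner scores the 30% "meta" part, giving six
meta-features per sample (class-0 and class-1 scores of SVM, CNN, MHA
in that fixed order).  The meta-classifier is a perceptron over these
six features.  Its published layer widths (12, 8, 2) are read as the
hidden/hidden/output widths — a first layer of width 12 cannot *input*
12 features when only six meta-features exist — giving
fc(6→12, ReLU) → fc(12→8, ReLU) → fc(8→2, softmax); the widths are
configurable.  It trains 100 epochs under softmax cross-entropy with
Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$;
unstated in the source material, so the standard values are used) at
lr 0.01 with cosine annealing,
$lr_t = lr_{\min} + \tfrac12(lr_{\max}-lr_{\min})(1+\cos(\pi t/T_{\max}))$,
annealed to $10^{-6}$.  A pair is called interacting iff
$P(y{=}1) > P(y{=}0)$, i.e. strictly above 0.5; ties classify as
non-interacting.

All neural components (conv/batch-norm/pool/attention/dense layers,
Adam, the scheduler) are implemented in the package with plain matrix
operations; training is seeded end to end, and two runs with the same
seed produce identical predictions.

# CCC scoring

Predicted interactions are kept iff probability $> \theta$ (strict;
default $\theta = 0.99$); known catalogue interactions bypass the
threshold.  Both must pass the expression filter: an interaction whose
ligand or receptor is absent from the matrix — or expressed in no cell
— is dropped.  "Expressed" means a strictly positive value, the
natural reading for count/TPM-like matrices.

For sender type $C_j$ and receiver type $C_p$, each filtered
interaction $(u, w)$ contributes three scores:

* **cell expression**: $(\hat c_{u,j}/\hat n_1)(\hat c_{w,p}/\hat n_2)$,
  the product of expressing-cell fractions;
* **expression product**: $\bar L_{u,j}\,\bar R_{w,p}$, the product of
  type means (zeros included);
* **specific expression**:
  $(\bar L_{u,j}/\sum_{j'}\bar L_{u,j'})(\bar R_{w,p}/\sum_{p'}\bar R_{w,p'})$,
  with a factor of 0 when its denominator vanishes.

Summing each score over interactions gives three $m\times m$ matrices
(all ordered type pairs including the diagonal — self-communication is
real biology; consumers may mask it).  Each matrix is min-max
normalized over **all** entries, diagonal included (the alternative,
excluding the diagonal, changes only the affine scale; including it
keeps the normalization a function of the reported matrix).  A constant
matrix normalizes to all zeros.  The final strength is the element-wise
PERT three-point estimate
$f = (g_{\max} + 4 g_{\mathrm{med}} + g_{\min})/6$, which always lies
within the envelope of the three normalized scores, hence in $[0, 1]$.

Per-pair interaction rankings are produced per method and for a
combined score defined as the three-point estimate of the three
per-interaction scores, each min-max normalized across interactions
within the pair.  The source material tabulates such combined rankings
without stating the rule; this definition mirrors the matrix-level
combination and is flagged as a package choice.  Ties break
deterministically by (score desc, ligand asc, receptor asc).

# Evaluation harness

Precision, recall, accuracy and F1 use the 0/0 → 0 convention so fold
reports never contain NaN.  ROC-AUC is the pairwise-ordering
probability with ties at one half (computed from ranks, verified
against a brute-force pair-counting oracle); AUPR is step integration
of the precision–recall curve with tied scores treated as one
threshold.  Cross-validation is stratified (the class ratio is
preserved per fold; stratification is not stated in the source
material but is the safer default for balanced fold metrics), shuffled
per repeat, 5 folds × 20 repeats by default, with fold-level (not
pooled) aggregation reported as mean ± sd.

# Synthetic data

The generators define the study conditions for the test suite:

* **Sequences**: uniform residues, lengths 50–200 — long enough for
  every encoder and representative of extracellular domain lengths.
* **Pair geometry**: positives $\mathcal N(0, I_d)$ with $d = 4$ by
  default; unlabeled candidates are a mixture of true negatives
  centred `separation` = 4 sigma away (shift spread evenly over
  coordinates) and 25% decoys drawn from the positive distribution.
  The decoy fraction models hidden positives among unlabeled
  ligand–receptor pairs, which are a minority in practice — most
  random pairs do not interact.  The default dimension is deliberately
  low: the centroid-distance rule is radial, and in high dimensions
  distances concentrate so strongly that no radial band can separate a
  mean-shifted cluster; 4 dimensions is the regime the rule is
  designed for.  Classifier fixtures use `genTwoClassData()` at width
  400 to match the pipeline's pair-vector width.
* **Expression**: Poisson(1) baseline counts; planted interactions
  multiply the ligand rate in sender cells and the receptor rate in
  receiver cells by `effect` = 10.  The multiplicative-rate design
  keeps "expressed = value > 0" meaningful.  Balanced types (3 × 50
  cells, 60 genes) keep fixtures fast.

What these fixtures do **not** emulate: sequence homology structure,
scRNA-seq dropout and library-size variation, unbalanced cell-type
abundances, and correlated gene programs.  Passing tests therefore
demonstrate correctness of the algorithms under clean, controlled
signal — not performance on real tissues.

# Problem sizes and numerical choices

The test suite and the acceptance script train the full-width ensemble
on a 400-sample, 400-feature fixture (one fit, reused across checks)
and keep every other fixture at tens-to-hundreds of samples; a full
suite run fits three base learners in well under two minutes on one
core.  Other numerical choices collected here:

* cross-entropy inputs are clamped to $[10^{-12}, 1-10^{-12}]$;
* batch-norm uses $\epsilon = 10^{-8}$ and biased batch variance;
* batches of size 1 are skipped during training (batch-norm needs at
  least two samples);
* PCA orthonormality is validated to $10^{-8}$;
* the negative-selection band treats boundary distances as inside;
* min-max of a constant matrix is defined as zero everywhere.

# Limitations

* The single-token attention learner cannot exploit intra-sequence
  structure; it functions as a regularized linear-projection network,
  which is exactly what its stated dimensions admit.
* The centroid-band rule assumes positives form one roughly isotropic
  cluster; multi-modal positive sets would need the multi-cluster
  generalization, which is out of scope.
* Known interactions carry no probability, so threshold sweeps affect
  only predicted pairs.
* CCC strengths are relative (min-max normalized per dataset); they
  are comparable within one analysis, not across datasets.
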