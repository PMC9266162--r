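---
title: "Predicting protein-protein binding sites from sequence profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein binding sites from sequence profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppisite)
```

## The problem

Protein-protein interactions are mediated by a minority of surface residues,
the interface or binding-site residues. Identifying them from sequence alone
matters because most known protein sequences have no solved structure.
`ppisite` treats the task as per-residue binary classification: every amino
acid of a chain is scored for membership in a protein-protein interface,
using three per-residue profiles that can all be computed from sequence
(two directly, one via structure prediction upstream):

* a **PSSM** (position-specific scoring matrix) from iterative database
  search, 20 log-odds values per residue — evolutionary conservation;
* an **HMM profile** (`.hhm`) from a profile hidden Markov model, 20
  match-emission probabilities per residue — a second, alignment-based view
  of conservation;
* **DSSP** output — an 8-class secondary-structure assignment, backbone
  torsion angles phi/psi, and solvent-accessible surface area.

Binding-site labels (a residue is an interface residue when its absolute
solvent accessibility changes by less than 1 Å² between the bound and
unbound states) are consumed as given; constructing them from complexes is
out of scope, as is running PSI-BLAST/HHblits/DSSP themselves.

## Feature encoding

Each profile becomes a per-residue feature matrix on a common 0-1 scale:

* **PSSM (L x 20)** — columnwise min-max scaling,
  $x' = (x - \min)/(\max - \min)$, with extrema taken over *all residues of
  all training chains*. Test-time values outside the training range are
  clamped to $[0, 1]$; a constant training column maps to 0.
* **HMM (L x 20)** — the `.hhm` integer $s = -1000\log_2 p$ is inverted to
  the emission probability $p = 2^{-s/1000}$; absent (`*`) cells become
  probability 0, matching their negligible-emission meaning; then the same
  min-max scaling, fitted on the probability scale.
* **DSSP (L x 14)** — a 9-state one-hot (the eight DSSP structure classes,
  with blank parsed as the loop class, plus a `NONE` state for residues the
  DSSP output does not cover), then $\sin\phi, \cos\phi, \sin\psi, \cos\psi$
  rescaled from $[-1,1]$ to $[0,1]$ via $(v+1)/2$, then relative solvent
  accessibility RSA $= \mathrm{acc}/\mathrm{maxASA}$, capped at 1.

Design points that were genuinely open, and the choices made:

* *Loop vs absence.* DSSP denotes loop/irregular structure by a blank
  column, and it is one of the eight structure classes; the ninth dimension
  is reserved for residues missing from the DSSP output entirely. Those
  missing residues get the `NONE` one-hot, neutral torsion values (0.5, the
  rescaled zero) and RSA 0.
* *Torsion rescaling.* The sine/cosine transform alone leaves values in
  $[-1,1]$; rescaling to $[0,1]$ keeps all 14 dimensions on one footing. A
  `trig_raw` switch in `encode_dssp()` preserves the raw variant.
* *maxASA scale.* The Tien et al. (2013) theoretical maxima; `X` uses the
  mean over the 20 residue types. Observed accessibilities above the maximum
  cap at RSA 1.
* *PSSM block.* The log-odds block (first 20 columns), not the weighted
  percentage block: log-odds is the conventional choice where only "20
  features" is specified.
* *No refit for DSSP.* The 14 structural dimensions are bounded by
  construction, so min-max statistics are fitted for the evolutionary
  features only.

Normalization statistics are first-class objects with a provenance tag
naming the training split that produced them, serialized to JSON at 17
significant digits so they reload bit-identically.

## Windows and model

Local context enters through a sliding window: residue $i$ contributes the
feature rows of residues $i-a \ldots i+a$ (window length $n = 2a+1$, default
19). Positions beyond the termini are zero vectors, so every residue yields
windows of identical shape and row $a+1$ is always the residue itself.

Each of the three $n \times m$ windows ($m = 20, 14, 20$ for PSSM, DSSP,
HMM) feeds its own convolutional branch: three stride-1 valid 1-D
convolutions along the window axis with kernels 5, 3, 3 and 64, 32, 16
filters, each ReLU-activated; then layer normalization over the final
(position, channel) output and a branch-specific dropout (0.1 PSSM, 0.3
DSSP, 0.2 HMM). The flattened branch outputs are concatenated — at $n = 19$
the extents are $15 \to 13 \to 11$, so each branch contributes
$11 \times 16 = 176$ and the joint vector is 528 wide — and classified by
dense layers of 256, 128, 64 ReLU units and a single sigmoid output. The
loss is binary cross-entropy, optimized by SGD with momentum.

Numerical and design choices:

* 1-D convolution along the window axis with features as channels, and
  *valid* (no-padding) convolution: padding would invent border values on
  top of the window's own zero padding.
* Branch order is fixed (PSSM, DSSP, HMM) for the concatenation, and
  per-branch flatten-then-concatenate is used (equivalent to
  concatenate-then-flatten up to a fixed permutation).
* No dropout in the dense head.
* Loss scores are clipped to $[10^{-7}, 1-10^{-7}]$, so the loss is finite
  even for saturated outputs; layer-norm variance is floored at $10^{-5}$.
* Inputs are centered by subtracting 0.5 before the first convolution. This
  is a pure reparameterization of the first-layer bias (the function class
  is unchanged) that conditions SGD better than the raw 0-1 features.
* Everything is seeded: parameter initialization (Glorot uniform),
  mini-batch shuffling and dropout masks, so a build-train-predict run is
  bit-reproducible.

The forward and backward passes are written directly in matrix algebra with
a small compiled core for the convolutions: the $(B, n, m)$ window tensor is
viewed as a $(Bn, m)$ matrix in which each kernel tap is a contiguous row
block, so convolution forward and backward are plain GEMMs. Gradients are
verified against central finite differences in the test suite.

## Training protocol

Training hyperparameters are not part of the published architecture; the
package defaults are SGD with learning rate 0.02, a 3-epoch linear warmup
followed by 0.90-per-epoch decay, momentum 0.9, batch size 256, 28 epochs,
and weight decay $3\times10^{-2}$ on weight matrices (not biases or
layer-norm parameters). Biases are
initialized at 0.1 so that, with centered inputs, the ReLU units start
active and optimization begins near the linear regime — in a
218k-parameter network trained on a few thousand windows, these choices
decide whether the convolutional weight sharing (the architecture's real
advantage at this sample size) is found or the dense head simply memorizes.
All are configurable, and `train_model()` optionally monitors a validation
batch with early stopping on AUPRC (patience 15), returning the best
parameters.

Evaluation follows the standard imbalanced-classification toolkit: ACC,
precision, recall, F1 and MCC at a threshold (0.5 by default;
`best_f1_threshold()` provides the F1-maximizing alternative since the
operating threshold of the published evaluation is unstated), plus
threshold-free AUROC (Mann-Whitney rank statistic, ties counting one half)
and AUPRC (step-wise precision-recall integration — trapezoidal
interpolation is optimistic on PR curves). Degenerate confusion tables are
reported as 0 (or `NA` for the ranking metrics) with an explicit flag rather
than `NaN`; MCC with a zero marginal is 0, flagged.

A convergence guard wraps the fold-level training used by cross-validation
and ablation: SGD on this architecture occasionally never leaves the
class-prior plateau, which is detectable from the training loss alone (it
stays near the base-rate entropy of the training labels). Such a run is
retried once with an offset seed and the better-optimized run is kept — a
selection that uses training loss only, so held-out data never leaks into
it.

Cross-validation splits by *whole protein* — residue-level splits would leak
near-duplicate overlapping windows between training and validation — and
normalization statistics are refitted inside each training split; their
provenance tag records the fold. The window-size scan repeats the
cross-validation for half-widths 4-14, and the ablation trains reduced
models (evolutionary = PSSM+HMM branches, structural = DSSP branch only)
against the full three-branch model on one shared protein-level split.

## What the synthetic generator emulates

Because the real benchmark profiles require PSI-BLAST/UniRef90,
HHblits/UniClust30 and DSSP runs, the package ships a generator that emits
the three file dialects with full ground truth:

* integer PSSM log-odds in $[-8, 12]$; `.hhm` scores in $[0, 6000]$ with
  about 2% `*` cells; secondary structure from a sticky Markov chain (so
  states come in runs, as in real assignments); phi/psi from
  Ramachandran-like per-state basins with the first phi and last psi
  undefined, as DSSP prints them; accessibility uniform up to the residue
  maximum.
* labels from a logistic model on configurable feature channels (default:
  PSSM column 1, HMM column 1, DSSP RSA) averaged over a ±8-residue
  neighbourhood and standardized; the intercept is calibrated by root
  finding to a target prevalence of 0.154, the interacting/total ratio of
  the merged benchmark sets. The default effect size 4 was fixed at design
  time from the label model alone: it puts the Bayes-optimal scorer (the
  generator's own logistic, exposed by `bayes_scores()`) at AUROC ≈ 0.96,
  so planted signal is strong but labels remain stochastic.

Because the signal is a *neighbourhood average*, wider context genuinely
helps, which is what makes the window-size scan meaningful on this data; and
because it spans ±8 residues, a window of 19 covers it while a window of 9
cannot.

What the generator does **not** emulate: real evolutionary covariance
between profile columns, real secondary-structure/accessibility coupling,
the spatial clustering of true interfaces, or the ΔASA labelling rule.
Passing the signal-recovery tests therefore demonstrates that the pipeline
(parsing, encoding, windowing, training, evaluation) is correct and can
recover planted signal at realistic prevalence — not that the model attains
the published benchmark numbers, which require the real datasets and profile
databases.

Default problem sizes used by the test suite and the acceptance script — 50
chains of 60-140 residues (about 5,000 residues), 5-fold protein-level
cross-validation, half-widths 4 and 9 for the scan — were chosen so a full
signal-recovery study runs comfortably on a single CPU.

## Known limitations

* Training is CPU-bound dense linear algebra; chains beyond a few thousand
  windows per batch are fine, but no GPU path exists.
* The sample-size regime of the synthetic study (≈4,000 training windows
  per fold) is small for a 218k-parameter network; the training recipe
  (weight decay, decaying learning rate, early stopping) exists to make
  that regime workable, and held-out ranking quality on synthetic data sits
  close to, but below, the Bayes ceiling.
* The `.hhm` parser reads match-emission scores only; transition and
  diversity columns are discarded by design.
* Multi-chain DSSP files are handled only to the extent of extracting one
  requested chain.
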