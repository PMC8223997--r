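---
title: "Reconstruction-based prediction of protein-protein interactions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction-based prediction of protein-protein interactions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aeppi)
```

## The model

Whether two proteins physically interact can be predicted, to a useful
degree, from their primary sequences alone. `aeppi` casts this binary
classification problem as a *one-class-modelling* problem solved twice.
Let $C^+$ be a set of interacting protein pairs and $C^-$ a set of
non-interacting pairs, each pair represented by a numeric vector. Two
autoencoders are trained: $AE^+$ only on $C^+$ and $AE^-$ only on $C^-$.
An autoencoder reconstructs inputs drawn from the distribution it was
trained on far better than inputs from elsewhere, so the two mean squared
reconstruction losses $L^+(p, p')$ and $L^-(p, p')$ of a new pair measure
its affinity to each class. They are converted to a probability of
non-interaction in closed form:

$$
pr^-(p,p') \;=\; \frac{1}{2} + \frac{L^+(p,p') - L^-(p,p')}
                                     {2\,\bigl(L^+(p,p') + L^-(p,p')\bigr)},
\qquad
pr^+(p,p') \;=\; 1 - pr^-(p,p'),
$$

so the pair is called *interacting* exactly when $L^+ < L^-$. The formula
is scale-invariant in the losses, bounded in $[0,1]$, and gives
$pr^- = 1$ whenever $L^- = 0 < L^+$. At $L^+ = L^-$ (including the
degenerate $0/0$ case) symmetry forces $pr^\pm = 0.5$; we resolve the tie
as *negative*, since the positive call requires a strictly smaller
$L^+$. No calibration against empirical frequencies is applied; the
closed form is used as is.

## Sequence featurization

Each protein is mapped to a fixed-length vector of length
$k = 343 + m \cdot \mathrm{lag}$, the concatenation (AC first, then CT)
of:

* **Conjoint Triad (CT).** The 20 amino acids are grouped into the seven
  classes of Shen and colleagues — {A,G,V}, {I,L,F,P}, {Y,M,T,S},
  {H,N,Q,W}, {R,K}, {D,E}, {C} — reflecting dipole and side-chain-volume
  similarity. A window of size 3 slides over the class-mapped sequence and
  the frequency of each of the $7^3 = 343$ ordered class triples is
  counted (index linearized first-position-major). Counts are normalized
  per protein; the default mode is min–max, $d_i = (f_i - \min f)/\max f$,
  matching the common descriptor-toolkit convention, with plain relative
  frequency $f_i/(L-2)$ available as `ct_normalization =
  "relative_frequency"`. Both modes are provided because published
  pipelines are not always explicit about which of the two they used.
* **Autocovariance (AC).** For each of $m$ physico-chemical property
  scales (standardized to zero mean and unit standard deviation over the
  20 residues; we use the sample SD — the choice only rescales features
  uniformly) and each offset $d \in 1..\mathrm{lag}$,

  $$\mathrm{AC}(j,d) = \frac{1}{L-d} \sum_{i=1}^{L-d}
     \bigl(x_i - \bar{x}\bigr)\bigl(x_{i+d} - \bar{x}\bigr),$$

  where $x_i$ is property $j$ of residue $i$ and $\bar{x}$ its mean over
  the sequence. This captures dependencies up to `lag` positions apart;
  `lag` must be smaller than every sequence length (we reject offending
  sequences with an explicit error rather than silently truncating).

The bundled property table carries 14 published scales (two
hydrophobicities, hydrophilicity, net side-chain charge, two polarities,
polarizability, solvent-accessible surface area, side-chain volume,
flexibility, accessibility, exposed surface, turn propensity, antigenic
propensity). Exact numeric provenance of such scales varies across the
literature; the table is deliberately *data*, not code
(`inst/extdata/aa_properties_14.tsv`), any $m \times 20$ table is
accepted, and autocovariance values are defined relative to the table
supplied. Sequences are cleaned first: every character outside the
20-letter standard alphabet (U, O, B, J, X, Z, gaps, ...) is removed.

A pair $(p, p')$ is the plain concatenation of the two protein vectors
($2k$ entries). Pairs are treated as *ordered* — features of the first
partner come first, as listed in the pair file — because the
concatenation has no canonical symmetrization.

## Architectures

All three variants share the layer recipe: encoder $\to$ 600 $\to$ 600
$\to$ 300 (bottleneck), mirrored decoder hidden widths (600, 600), SELU
activations throughout, and a *linear* output layer (AC features are
signed, so a bounded output nonlinearity would be wrong with MSE).

* `joint_joint` — one network consumes and reconstructs the full $2k$
  pair vector.
* `siamese_joint` — a weight-shared encoder maps each protein to a
  300-wide code ($z$, $z'$); the decoder reconstructs the $2k$ pair from
  `concat(z, z')`.
* `siamese_siamese` — shared encoder as above; the combined code
  $\hat z = z \odot z'$ (element-wise product) is concatenated with each
  protein's own code, and a *shared* decoder maps `concat(z, zhat)` to a
  reconstruction of $p$ and `concat(z', zhat)` to a reconstruction of
  $p'$; the loss is the mean of the two per-protein MSEs (equal to the
  MSE over the concatenated $2k$ reconstruction). Because encoder and
  decoder are shared and $\odot$ commutes, this loss is exactly invariant
  under swapping the partners — a property the joint variants do not
  have, and which the test suite asserts in both directions.

Where the published description leaves the siamese decoders'
re-expansion path open, we pin the minimal mirrored reading: decoder
input is the stated 600-wide concatenation, hidden widths mirror the
encoder (600, 600), and the final linear layer is sized to the
reconstruction target ($2k$ or $k$).

Training is minibatch Adam (batch 64) on the MSE, initial learning rate
$5\times10^{-4}$, for 2000 epochs in the reference recipe; 10% of the
training pairs (seeded split) are held out for validation, and the
learning rate is halved whenever 5 consecutive epochs pass without a
strictly lower validation loss, floored at $10^{-5}$. "Improvement"
means strictly better than the best value seen so far, with no minimum
delta. Final-epoch weights are returned; best-validation checkpointing
exists behind `keep_best = TRUE` (default off, matching the plain
schedule). Weights are LeCun-normal initialized — the standard companion
of SELU — from a caller-supplied seed, and a single seed fans out
deterministically to initialization, splits, and batch shuffling, so
identical inputs give byte-identical models. The networks are
implemented directly on BLAS-backed matrix operations with a fused
in-place Adam step in C++; the backward pass of every architecture is
verified against numerical differentiation in the test suite.

## Evaluation protocol

Metrics come from the standard confusion matrix (positive =
interacting): accuracy, precision, recall, specificity, F1, and
`auc_balanced` $= (\mathrm{specificity} + \mathrm{recall})/2$. The last
is the protocol's "AUC"; it is *balanced accuracy*, not the rank-based
area under the ROC curve, and we name it accordingly. A conventional
rank-based AUC over $pr^+$ scores is available via `roc_auc()` for
diagnostics only. Degenerate denominators (e.g. no predicted positives)
yield 0 with a warning instead of NaN, so confidence intervals never
propagate missing values.

`cross_validate()` shuffles and partitions each class into $k$ folds
*independently* (training is per-class by construction, so per-class
stratification is the natural reading; $k=5$ gives 80/20 splits, $k=10$
gives 90/10). Per-fold means are summarized with a Student-$t$ 95%
interval, $\bar m \pm t_{0.975,\,k-1}\, s/\sqrt{k}$ with $s$ the sample
standard deviation — the standard small-sample interval for $k \le 10$
folds.

## Synthetic data

Real benchmark corpora (curated interaction databases with
subcellular-localization-based negatives) are external downloads; the
package instead ships a seeded generator so the whole pipeline is
testable offline. It emulates: variable-length sequences (uniform in
`length_range`, default 50–300) over the 20-letter alphabet, an
i.i.d. residue background (uniform by default; a skewed preset stresses
normalization), and two pair classes separated by a planted, learnable
signal.

The signal mechanism is **motif co-occurrence**, mirroring the intuition
of complementary interface motifs: 30% of proteins are "baits" carrying
copies of the first library motif, 30% "preys" carrying the second, 40%
motif-free background. Interacting pairs are (bait, prey) pairs;
non-interacting pairs are drawn among background proteins. Each carrier
receives its motif with probability `signal_strength` (so 0 yields
exchangeable null classes and 1 a fully penetrant signal). The default
motifs, `CCCCCCCCCCCC` and `RKRKRKRKRKRK` (two copies each, overwritten
at non-overlapping positions), are 12-mers over the two *rarest*
conjoint classes ({C} and {R,K}), chosen so the planted signal lands on
a few specific CT triads — the channel the autoencoders must encode —
while the AC channel is perturbed only weakly. The generator does not
attempt realistic interaction-network topology (hubs, degree
distributions) or localization-based negative sampling; passing tests on
it demonstrate that the pipeline recovers a compositional signal, not
that it reproduces performance on curated biological corpora.

## Problem sizes and numerical choices

The reference recipe (2000 epochs on corpus-scale data) is not what the
test suite runs. `desk_training_config()` is the package's desk-scale
preset: 50 epochs with the full 600–600–300 widths and otherwise
unchanged hyperparameters. The end-to-end experiment in the acceptance
suite uses 400 proteins, 1000+1000 pairs, full signal, `lag = 5`, three
property scales, and 5-fold cross-validation of both the
Siamese–Siamese and Joint–Joint variants under that preset; unit tests
use further-reduced widths (overridable in `build_autoencoder()`) so
each trains in seconds.

Other choices worth stating: CT min–max normalization divides by the
maximum count (so the minimum maps to 0 and, whenever some triad is
absent — always the case at realistic lengths — the maximum to 1);
triad indices are pinned first-position-major purely for
reproducibility; sequences equal in length to `lag` or shorter than 3
residues are rejected at featurization rather than padded; and the
probability formula's $0/0$ case is defined by symmetry rather than
special-cased downstream.

## Limitations

* Autocovariance values are defined relative to the property table in
  use; two installations exchanging models must share the table (the
  descriptor fingerprint embedded in models and feature matrices guards
  against silent mismatch).
* The closed-form probability is a monotone transform of the loss gap,
  not a calibrated posterior.
* Ordered-pair featurization means a pair and its reverse may receive
  different scores under the joint architectures; the Siamese–Siamese
  variant is the symmetric choice.
* Performance claims on synthetic data bound nothing about curated
  interaction corpora; the generator's signal is deliberately clean.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
scfg <- synthesis_config(n_proteins = 120, n_pos = 150, n_neg = 150,
                         lag = 5, seed = 7)
ds <- generate_ppi_dataset(scfg)
dcfg <- descriptor_config(lag = 5,
                          property_table = read_property_table()[1:3, ])
report <- cross_validate(ds$proteins, ds$pairs, k = 5,
                         arch = "siamese_siamese",
                         tconfig = desk_training_config(seed = 1),
                         dconfig = dcfg, seed = 1)
report
```

See the README for the printed output of this run and the shell
equivalents (`aeppi simulate | featurize | train | predict | evaluate`).
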