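---
title: "Predicting protein solubility from sequence: the solupred pipeline"
author: "solupred authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein solubility from sequence: the solupred pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Only a minority of heterologously expressed proteins fold into soluble
product in *E. coli*; the rest aggregate into inclusion bodies. A
sequence-only solubility predictor lets expression pipelines prioritize
constructs before any wet work. `solupred` implements such a predictor
as a fully inspectable pipeline: physicochemical descriptor encoding, a
genetic-algorithm (GA) feature selector, a skip-gram k-mer embedding,
and a soft-voting ensemble of LSTM classifiers, together with the
evaluation metrics and a synthetic-data generator that makes every
stage testable offline.

## Feature representation

Three feature groups are concatenated into the hybrid vector fed to the
classifier.

**Five descriptor families (523D with defaults).** Amino-acid
composition (20D), dipeptide composition (400D), the composition
component of the CTD scheme over 13 residue groupings (39D),
amphiphilic pseudo-amino-acid composition (APAAC, `20 + 2*lambda` D)
and the quasi-sequence-order descriptor (QSOrder, `40 + 2*nlag` D).
The total width is `20 + 400 + 39 + (20 + 2*lambda) + (40 + 2*nlag)`;
the defaults `lambda = 1`, `nlag = 1` give the canonical 523 columns
(the minimal symmetric choice with `lambda + nlag = 2`). Both
parameters stay configurable through `descriptor_spec()`.

APAAC standardizes the hydrophobicity and hydrophilicity scales over
the 20 residues and couples residues at lags `1..lambda`; with relative
residue frequencies the whole vector is normalized to sum to one. Its
order-term weight defaults to the conventional 0.05. QSOrder couples
residues through two distance matrices with squared-distance sums at
lags `1..nlag` and weight 0.1. The Grantham matrix is computed from the
published composition/polarity/volume formula (coefficients 1.833,
0.1018, 0.000399, scaled to mean 100 over distinct pairs), which
reproduces the published table. For the Schneider–Wrede-style
physicochemical distance we ship a *reconstruction* — Euclidean
distance over the standardized hydrophobicity / hydrophilicity /
side-chain-mass triplet, rescaled to `[0, 1]` — because the original
table is not available as a redistributable resource here; a
user-supplied matrix can be passed to `qsorder()` to use the original.
The 13 CTD groupings ship as an editable text resource
(`ctdc_groupings()`); we use the standard seven hydrophobicity
partitions plus normalized van der Waals volume, polarity,
polarizability, charge, secondary structure and solvent accessibility.

**19 global features.** Fifteen sequence-level properties (length,
molecular weight, isoelectric point by Bjellqvist-pK bisection on
4.05–12, Kyte–Doolittle gravy, aromaticity, instability index, mean
windowed Vihinen flexibility, helix/turn/sheet-former fractions,
charged-residue fraction, charge at pH 7, two extinction coefficients,
lysine fraction), three transmembrane-topology features, and one
maximum-identity-to-reference feature. The flexibility window is the
clean symmetric 9-residue Vihinen window (weights
`0.25, 0.4375, ..., 1, ..., 0.25` over 5.25); some popular
implementations off-center this window, which we deliberately do not
reproduce. Transmembrane features come from a built-in
hydropathy-window caller (19-residue Kyte–Doolittle windows, mean >
1.6; residues covered by candidate windows, a soft expected-window
count, and a positive-inside-rule N-terminus indicator) or from any
precomputed per-id table, so the 19-column contract is testable with no
external topology predictor. The identity feature is the maximum 3-mer
containment against a reference set (the training sequences by
default, self-matches excluded, reference capped at 500 evenly spaced
sequences); precomputed identities are accepted by table. When no
provider is available the column is set to the flagged sentinel `-1`
with a warning — never silently zero.

**k-mer embedding (100D).** Each sequence becomes its overlapping
k-mers at stride 1; a skip-gram model with negative sampling embeds
every k-mer and a sequence is the mean of its k-mer vectors. The
defaults are `k = 3`, window `w = 2` and 100 dimensions;
`grid_search_kw()` searches `k` in 2–6 and `w` in 1–7 with an
injectable downstream evaluator when retuning is wanted. The remaining
training choices are fixed as: min-count 1 (protein 3-mer vocabularies are small, at
most 8000), 10 epochs, 5 negative samples, initial learning rate 0.025
with linear decay. The trainer is seeded and single-threaded, so equal
inputs give bit-identical vectors. At prediction time, out-of-vocabulary
k-mers are skipped and the mean renormalized over known k-mers
(zero-imputation would drag embeddings toward the origin); an entirely
unknown sequence maps to the zero vector with a warning. The embedding
is trained on training sequences only and frozen before test sequences
are embedded, preventing leakage.

## Feature selection

The GA searches 100-column subsets of the 523 descriptor columns:
200 chromosomes, two-point crossover with duplicate-gene repair,
stochastic tournament selection (size 3, the common default),
per-individual mutation probability 0.0003
(when an individual mutates, one gene is resampled from the unused
indices; a per-gene interpretation is available by flag), and 500
generations in the full protocol. One elite chromosome is copied
unchanged per generation — also an open choice — which makes the
per-generation best fitness monotone and gives the selection its
regression test. Fitness is cross-validated accuracy of a base
classifier on the subset's columns, with AUC recorded alongside; the
returned subset is the best chromosome of the generation with maximum
AUC, not the final generation.

The base classifier is injectable: a linear SVM (`e1071`), LDA,
logistic regression, or the package's closed-form diagonal LDA
(`"dlda"`). For simulation-scale studies we use `dlda` with 3-fold CV;
its fit is two means and a pooled variance per column, which keeps a
200-chromosome, 50-generation run on a 1000 x 523 matrix in the
~1–2 minute range on one core without changing what the GA is testing
(recovery of mean-shifted columns). An F-score ranking
(`fscore_rank()`) plus sequential forward search (`sfs_select()`)
provides the classical two-step baseline; importance rankings from
external tools can be fed to `sfs_select()` directly.

## The classifier

The 219-column hybrid vector (100 selected descriptors, 100 embedding
dimensions, 19 global features) is standardized column-wise (z-score;
the scaler is stored with the model) and unrolled as 219 timesteps of
one feature into a single LSTM layer, followed by two ReLU fully
connected layers, dropout, and a 2-class softmax. Training uses Adam on
categorical cross-entropy with early stopping on validation loss and
restoration of the best-epoch weights. The unrolling direction (one
feature per timestep) is the standard reading of feeding a flat vector
to an LSTM; the forget-gate bias is initialized to 1, weights are
Glorot-uniform from a seeded generator, and training is
single-threaded, so a full train–predict cycle is reproducible from
`(seed, config, data)`.

The ensemble follows the 10-fold protocol: a stratified split into ten
folds; model *k* trains on the other nine and validates on fold *k*;
prediction soft-votes the ten members (mean soluble-class probability)
at decision threshold 0.4, stored with the model rather than
hard-coded. Hyperparameter search (`tune_hyperparams()`) samples LSTM
units from {32, 64, 128}, the two FC widths from {16, 32, 64} and the
learning rate log-uniformly on [1e-4, 1e-2] — the package's default
search space — and keeps the best validation-accuracy configuration. Feature selection and the embedding
are fit once on the full training set and shared by all ten members.
As a model-inspection substitute for game-theoretic attribution the
package provides seeded permutation importance
(`permutation_importance()`).

## Evaluation

`binary_metrics()` evaluates accuracy, sensitivity (SN), specificity
(SP), the Matthews correlation coefficient and the balance statistic
`|SN − SP| * 100` directly from confusion counts, with soluble as the
positive class; values are stored at full precision and rounded only
for display. A zero MCC denominator yields 0 with an explicit flag.
`roc_auc()` sweeps thresholds over tie-grouped scores and integrates by
trapezoid, which equals the pairwise-concordance (Mann–Whitney)
statistic with half-credit ties; the test suite asserts that equality
to 1e-12.

## Synthetic data

`generate_dataset()` draws balanced soluble/insoluble sequence sets
whose label correlates with residue composition: the soluble class is
tilted toward charged residues (K, R, D, E) and turn formers (G, N, S)
and away from hydrophobic residues, the insoluble class oppositely,
each residue's sampling log-probability shifted by
`±effect_size/10` along the signal direction. At `effect_size = 2` the
charged+turn fraction moves by roughly 0.15 between classes — strong
enough that a competent pipeline should approach perfect ranking —
while `effect_size = 0` makes the classes exchangeable, so downstream
AUC must collapse to 0.5. Label noise flips labels with a configured
probability. The signal is deliberately planted in *composition* (AAC,
CTD, global-feature channels), so selector and importance analyses have
a known ground truth, and order-sensitive channels receive only
incidental signal. What passing these tests shows is that the pipeline
recovers compositional signal at realistic sequence lengths; it does
not show that real solubility, which also depends on structure, host
and expression context, is equally recoverable.

`generate_feature_matrix()` is the tabular analogue (standard normal
columns, a chosen number of them mean-shifted between classes) used to
study the GA directly.

## Numerical and scale choices

Descriptor computations are exact arithmetic; the suite checks every
family against independent loop-level formula transcriptions at 1e-10.
Sequences shorter than `max(k, lambda + 1, nlag + 1)` are rejected by
the stage that needs them. Zero-variance columns get unit scale in the
standardizer. Degenerate metric cases (single-class folds, zero MCC
denominators, all-out-of-vocabulary sequences) raise errors or flagged
sentinels rather than silent defaults.

Verification runs are sized for a single CPU core: GA recovery uses
1000 x 523 matrices with 10 informative columns, 50 generations and
the `dlda` fitness; classifier recovery uses 2000 sequences per class,
a 16-unit LSTM, batch 128 and at most 12 epochs; the determinism check
uses an intentionally tiny end-to-end run. These sizes are the
package's own verification conditions; the full-scale protocol
(500 GA generations, larger networks, benchmark-sized datasets) is
available by configuration.

## Known limitations

- The physicochemical distance matrix behind half of QSOrder is a
  documented reconstruction, not the original published table (which
  can be supplied by the user).
- The built-in transmembrane caller is a hydropathy-window heuristic,
  not an HMM topology predictor; for serious use supply a precomputed
  topology table.
- The 19-feature list covers the properties most often highlighted by
  model-interpretation analyses of solubility predictors (isoelectric
  point, gravy, aromaticity, flexibility, instability, molecular
  weight, charge and structure fractions, topology, identity); the
  remaining slots (extinction coefficients, pH-7 charge, lysine
  fraction, length) are this package's choices.
- Real-data performance of sequence-only solubility predictors is
  modest (sub-0.6 accuracy on stringent benchmarks); the synthetic
  recoveries here validate the machinery, not biological performance.
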