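---
title: "Methods: stacked ensemble prediction of pseudouridine sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked ensemble prediction of pseudouridine sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psistack)
```

## The problem

Pseudouridine (Ψ) is the most abundant post-transcriptional RNA
modification: an isomer of uridine produced at specific uridine positions.
Experimental mapping of Ψ sites is expensive, so sequence-based predictors
are trained on fixed-length RNA fragments centred on a uridine — the centre
U is the candidate site, the flanking context carries the signal. Benchmark
sets in this area use balanced positive/negative fragments of 21 nt
(*H. sapiens*, *M. musculus*) or 31 nt (*S. cerevisiae*), with positives
confirmed experimentally.

psistack implements the full prediction pipeline: sequence encoders,
chi-square + incremental feature selection, a stacking ensemble, a
complete evaluation harness, and a synthetic-data generator that plants a
controllable class difference so everything can be exercised and tested
without external downloads.

## Encodings

Six schemes transform a fragment of length $L$ (odd, centre U) into a
numeric vector. For the stateless schemes, with alphabet order
A < C < G < U throughout:

| scheme  | idea | dimension | L = 21 | L = 31 |
|---------|------|-----------|-------:|-------:|
| binary  | per-position one-hot, A=(1,0,0,0) … U=(0,0,0,1) | $4L$ | 84 | 124 |
| NCP     | chemical-property triple per base: A=(1,1,1), C=(0,0,1), G=(0,1,0), U=(1,0,0) | $3L$ | 63 | 93 |
| ENAC    | sliding-window nucleotide frequencies (window $w$) | $4(L-w+1)$ | 80 | 120 |
| PS2     | positional dinucleotide one-hot (16 bits/pair) | $16(L-1)$ | 320 | 480 |
| PS3     | positional trinucleotide one-hot (64 bits/triple) | $64(L-2)$ | 1216 | 1856 |
| PSTNPss | fitted positional trinucleotide propensity | $L-2$ | 19 | 29 |

The NCP triple encodes three binary chemical classes — hydrogen-bond
strength (weak: A,U), ring structure (purine: A,G) and functional group
(amino: A,C) — so the mapping is injective on the four bases.

ENAC's window defaults to 2. The scheme is usually described with a
default window of 5, but the 21/31-nt feature spaces this package targets
(80 and 120 ENAC features) correspond to $4(L-1)$, i.e. $w = 2$; the
window remains a parameter for users who want the wider composition
context. ENAC emits frequencies (count/window) rather than raw counts so
values are comparable across window sizes.

### The PSTNPss propensity encoder

Position-specific trinucleotide propensity (single strand) is the one
*fitted* encoder. From a labelled training set it builds the
$64 \times (L-2)$ matrix

$$Z_{ij} = F^{+}(\mathrm{3mer}_i \mid j) - F^{-}(\mathrm{3mer}_i \mid j),$$

the difference between the relative frequencies of trinucleotide $i$
starting at position $j$ among positive and negative training sequences
(plain frequencies, no pseudocount — degenerate only if a class is empty,
which is rejected). A sequence is then encoded as the $L-2$ vector whose
$u$-th entry is $Z$ at the observed trinucleotide starting at $u$. Useful
identity (tested against a brute-force oracle): the per-position
difference of class means of the encoded training data equals
$\sum_i Z_{iu}^2 \ge 0$.

Because $Z$ is computed from class labels, *where* it is fitted matters:

* **fold-refit** (default for cross-validation): $Z$ is refit inside every
  CV fold on the training partition only. This is the leakage-safe
  protocol; it is what `cross_validate_sequences()` and the pipeline
  default do.
* **whole-training**: $Z$ is fitted once on the full training set, then CV
  is run on the resulting feature table. This mimics pipelines that encode
  first and cross-validate second. It *leaks* held-out labels: in our
  label-shuffled control the whole-training protocol reports ~84% accuracy
  where truth is 50%, which is precisely why it is not the default. It is
  retained, flagged, because feature selection on a single encoded table
  implies it, and reported results carry the mode used.

For an independent test set there is no ambiguity: $Z$ is fitted on the
training data and applied to the test sequences.

## Feature selection

Features are ranked by a chi-square score: each feature is min–max scaled
to $[0,1]$ (propensity features are negative-valued, and the scaling also
makes the score invariant to affine rescaling of any feature), then the
observed per-class sums of the scaled feature are compared with their
expectation under the class proportions, $\sum_c (O_c - E_c)^2 / E_c$.
Constant features score 0; ties in the ranking break by original column
index (parsimony and determinism; any rule would do, this one is stable).

Incremental feature selection (IFS) then walks prefixes of the ranking:
for each prefix size the chosen classifier (logistic regression by
default) is cross-validated on the top-$k$ features, all prefixes sharing
one stratified fold assignment so curve points differ only in the feature
set. The selected size is the *smallest* prefix attaining the maximum of
the accuracy curve. `combine_schemes()` applies the same greedy idea one
level up: schemes are ordered by single-scheme CV accuracy and cumulative
concatenations evaluated, flagging the best (smallest on ties).

## The stacking ensemble

Four base learners are supported, each with fixed defaults in the spirit
of common toolkit defaults: random forest (100 trees), logistic
regression (ridge penalty, $\lambda = 1/n$, matching the usual C = 1.0
regularised default; a single-feature design falls back to an unpenalised
fit), SVM (RBF kernel, cost 1.0, $\gamma = 1/p$, probability outputs) and
Gaussian naive Bayes (variance floored at $10^{-6}$ so one-hot features
constant within a class keep finite densities). Wider tuning grids (trees
100–1000, cost 1–15, $\gamma = 2^{-10}..2^5$) are exposed through
`grid_search()` but defaults are used for every reference run.

Training (`train_stacking()`) has two steps. Step 1 builds the
meta-feature matrix: within a stratified $k$-fold split, every base
learner is trained on $k-1$ folds and its positive-class probability on
the held-out fold recorded, so each training sample's meta-features come
from models that never saw it. Step 2 fits the meta-classifier (logistic
regression by default) on these out-of-fold probabilities. For
deployment, the base learners are refit on the full training set; a
prediction runs sample → base probabilities → meta probability, with
labels thresholded at 0.5 (classes are balanced by construction).
Probabilities rather than hard labels are used as meta-features because
they preserve ranking information and keep AUC meaningful.

## Evaluation

Sensitivity, specificity and accuracy follow the standard confusion-table
definitions; MCC is the standard Matthews correlation. Any metric with a
zero denominator is reported as `NA`, never silently 0. AUC is computed by
Mann–Whitney pair counting (ties = 1/2) via midranks, and the ROC
staircase is traced with 1−Sp as abscissa and Sn as ordinate; the
trapezoidal area under the staircase equals the pair-count AUC to 1e−9
(both identities are under test, including a cross-check against pROC).

Cross-validation is stratified with a caller-supplied seed; the canonical
report is computed on the predictions pooled over all held-out folds
(deterministic, and well-defined for AUC), with per-fold reports also
returned.

## The synthetic-data generator

`simulate_psi_dataset()` emulates the *structure* of the benchmark sets:
balanced classes, odd length with centre U, and a class difference
expressed at the trinucleotide level — at each designated signal position
a designated 3-mer is planted in positives with probability `delta`
(negatives always draw from the background, uniform by default), so
`delta = 0` makes the classes identically distributed and the planted
signal is exactly what the propensity and positional-trinucleotide
encoders are built to detect. Signal windows may not overlap, and a
window covering the centre must plant U there. Defaults: 200 fragments
per class, L = 21, three signal positions placed clear of the centre,
`delta = 0.5` — enough to be learnable but not trivially separable at
these sample sizes.

What passing tests on these data do **not** show: real Ψ-site context is
not three independent planted trinucleotides on a uniform background;
composition bias, positional correlation and motif degeneracy in real RNA
are absent. The generator validates the machinery (encoders, selection,
stacking, evaluation), not biological accuracy on any species.

## Numerical and design choices

* Positions are 1-based everywhere; the centre is $(L+1)/2$.
* Input normalization uppercases and maps T→U, since public benchmark
  files mix DNA and RNA alphabets; anything outside A/C/G/U/T is an error
  naming the offending position.
* Fold assignment: per class, a seeded shuffle is dealt round-robin into
  folds, guaranteeing both classes in every fold whenever each class has
  at least `folds` members.
* Seeds: every stochastic stage takes an explicit integer seed;
  sub-stage seeds are derived deterministically and kept within 32-bit
  range. Identical configs give byte-identical metrics files.
* Ties: smallest feature count / earliest index everywhere a tie can
  occur (IFS optimum, ranking order, best-combination flags).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
signal-recovery runs use 400 samples (200/class, L = 21, `delta = 0.8`,
PSTNPss + PS3, stacked RF + LR, 5-fold fold-refit CV), the label-shuffled
null uses 500 samples, chi-square localisation uses 10 replicates of 400,
and the IFS demonstration uses a 150 × 15 table with signal confined to
the three top-ranked features. These sizes give stable pass/fail
behaviour for the properties being checked while keeping a full run in
the minutes range on a single core.

## Limitations

* The published benchmark FASTA sets are optional external downloads;
  `run_benchmark()` reproduces the reference architecture on them
  (PSTNPss + PS3, RF + LR stacking, 5-fold CV) but agreement with
  published figures can only be approximate given unreported seeds and
  the PSTNPss fitting-scope ambiguity described above.
* Only the four selected base learners are implemented; boosting-family
  alternatives screened and rejected in the original model search are out
  of scope, as are probability calibration and class-imbalance handling.
* The ridge-penalised logistic regression mirrors a common default rather
  than exactly replicating any particular solver's path; on separable
  data its probabilities saturate like any unregularised fit would.
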