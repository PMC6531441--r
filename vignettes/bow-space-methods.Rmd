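---
title: "Methods: the bow-pharmacological space and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bow-pharmacological space and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`bowdti` predicts whether a protein and a small molecule interact by
classifying the pair in a joint 439-dimensional descriptor space with three
sub-spaces:

* **Protein space (107 dimensions).** Ten feature sets computed from the
  amino-acid string alone: the composition vector CV (20), first- and
  second-order composition moment vectors CMV (2 x 20), and three
  physicochemical descriptors over seven property scales — the summed basic
  values BPC (7), the neighbourhood contrast NPC (7), and the index-based
  sequence-order correlation IPC (7) — plus five group-composition sets over
  R-group, electronic, exchange, hydrophobicity, and side-chain groupings
  (5 + 5 + 6 + 4 + 6).
* **Ligand space (166 dimensions).** The MACCS structural-key fingerprint
  MACCSL: one bit per substructure key.
* **Interaction space (166 dimensions).** MACCSP, the element-wise mean of
  the MACCS fingerprints of the protein's known ligands in a supplied
  interaction network. This is where knowledge of the existing interactome
  enters the descriptor.

The headline classifier is a probit Bayesian additive regression trees
(BART) model implemented in compiled code inside the package: a sum of `m`
regularized trees fitted by backfitting MCMC with truncated-normal data
augmentation, returning a posterior-mean interaction probability and a
central posterior interval per pair. Four standard baselines (logistic
regression, RBF-kernel SVM, CART decision tree, random forest) run on the
same matrix behind the same `classifier_spec()`/`train_classifier()`
surface. Probabilities are thresholded by the strict rule: a pair is called
an interaction only when its probability exceeds 0.5; exactly 0.5 is a
non-interaction.

## Descriptor conventions and edge cases

* Residue order is alphabetical (A, C, D, ..., Y) throughout; sequences
  containing non-canonical letters are rejected unless a permissive mode
  drops them with a logged count.
* CMV positions are 1-based; the order-k normalizer is
  N(N−1)...(N−k). A zero normalizer (N <= k) is a degenerate-length error.
  Order 0 collapses to CV, which the tests assert on random sequences.
* The IPC lag term compares positions i and i+k for every lag k = 1..N−1;
  the k-th correlation factor is the mean squared difference of standardized
  property values at that lag, and IPC averages the factors over lags. On a
  homopolymer every factor is zero. Property standardization uses the
  sample standard deviation across the 20 residues.
* NPC sums |P_i² − P_{i−1}·P_{i+1}| over interior positions only
  (i = 2..N−1), since the boundary terms are undefined; sequences shorter
  than 3 yield zeros with a warning.
* BPC is the raw per-residue sum, hence length-dependent by construction;
  BPC and NPC use raw property values, IPC uses standardized ones.
* The seven property scales (hydrophobicity, charge, polarity, volume,
  flexibility, isoelectric point, refractivity) ship as one fixed,
  documented 20 x 7 table assembled from standard literature scales
  (Kyte–Doolittle, Grantham, Zamyatnin, Bhaskaran–Ponnuswamy, Zimmerman,
  Jones). Descriptor values are comparable only under a declared table;
  a user table can be supplied as CSV.
* The electronic grouping covers 19 residues — cysteine belongs to no
  printed electronic group — so that sub-block sums to 1 − CV_C, whereas
  the R-group, exchange and hydrophobicity sub-blocks sum to exactly 1.
  Side-chain groups overlap by design, so a residue can count several times.
* MACCS keys are computed with the open SMARTS dictionary of OpenBabel
  (through ChemmineOB); the package emits exactly the 166 informative keys
  as `maccs_1..maccs_166`. Different MACCS dialects disagree on individual
  keys, and the pipeline consumes bits generically, so no bit-for-bit parity
  with any particular chemistry suite is asserted. Pre-computed fingerprint
  tables are accepted and validated instead of structures.
* A protein with no known ligands (an orphan) gets an all-zero MACCSP with
  a warning rather than an error, so pairs involving unknown proteins stay
  predictable.

## Leakage control for the interaction space

MACCSP is the one descriptor block that depends on the labels' source — the
known-interaction network — so which edges enter the average decides whether
an evaluation is honest. `featurize_pairs(..., exclude_self = TRUE)`
implements leave-one-out averaging: a labelled pair's own edge never enters
its own MACCSP. `make_benchmark()` defaults to this mode; the alternatives
("train": drop the test portion's positive edges from the network; "all":
average everything) are retained for comparison with the permissive protocol.

## BART settings

Defaults: `m = 50` trees, 200 burn-in and 800 kept draws, leaf prior
N(0, tau²) with tau = 3/(k·sqrt(m)) and k = 2, structure prior
alpha·(1+depth)^(−beta) with alpha = 0.95, beta = 2, 100 uniformly spaced
cutpoints per variable, birth/death structural moves. The latent scale is
probit, so the prior keeps the latent function mostly within ±3. These
sampler settings are package choices (the classifier is defined by its
contract: posterior-mean probability plus central interval). Logistic
regression and the SVM consume per-column standardized features fitted on
training data only; tree ensembles consume raw features. The SVM uses the
stated gamma = 1e−4 and cost = 100; logistic regression is effectively
unpenalized.

## Gold-standard construction

Positives are the (unique) edges of the supplied network. Negatives are
sampled uniformly without replacement from the cross product of protein and
ligand pools disjoint from every entity in the positives; pairs listed in a
supplied exclusion set (e.g. background known edges) are never drawn. The
negative:positive ratio defaults to 1:1 and is recorded in the run manifest
because accuracy is ratio-sensitive. The 70/30 split and the 10 folds are
label-stratified by default (largest-remainder allocation keeps each class
within one pair of its exact share); a flag disables stratification.

## What the synthetic benchmark emulates

The generator plants signal at the class/prototype level. Protein classes
draw residue-frequency profiles from a symmetric Dirichlet; ligands derive
from prototype fingerprints — each prototype combines a few exclusive
signature keys with a shared random background — with independent per-bit
flips; and edges follow a class x prototype compatibility table in which
every prototype has a cognate class plus sparse off-block entries. The edge
law is `density · ((1−signal) + signal · compat / mean(compat))`, so the
expected interactome size is the same at every signal level, `signal = 0`
is pure bipartite noise, and `signal = 1` confines edges to compatible
blocks. Because a protein's partners concentrate on compatible scaffolds,
MACCSP genuinely carries the protein-side information that the bow space is
meant to exploit.

Two pair protocols are provided, and the distinction matters more than any
other design choice in the package:

* **Matched (default).** Every protein and ligand occurs in exactly one
  labelled pair. Cross-validated performance then measures generalization
  over the planted compatibility structure alone. Under this protocol the
  information ceiling is set by the compatibility geometry (roughly 0.91
  AUC at the default settings — the cosine similarity between MACCSL and
  MACCSP, an oracle with full knowledge of the mechanism, attains about
  that), kernel and ensemble methods approach it, and a linear model cannot
  express the class-prototype match at all. Ablating the MACCSP block
  lowers AUC because the interaction space is the cleanest carrier of the
  protein-side signal.
* **Pooled.** Entities are reused across pairs exactly as in the classical
  gold-standard protocol: positives reuse the gold entities, negatives come
  from disjoint pools. Because a pooled negative's protein or ligand never
  occurs in any positive, entity identity — recoverable from the
  near-unique continuous descriptors — separates the labels by itself, and
  every classifier reaches near-perfect cross-validated AUC regardless of
  planted signal strength. This is a property of the protocol, not of any
  classifier; the pooled mode exists precisely to reproduce that protocol,
  and all performance measured under it should be read as including a
  transductive entity-recognition component.

The zero-signal null control therefore uses the matched protocol: it is the
setting in which "no planted signal" implies "no attainable discrimination",
and the suite checks that every classifier then sits at chance. Matched-mode
defaults (2200 proteins, 3200 ligands, 12 classes, 12 prototypes, density
0.015, flip rate 0.04, Dirichlet concentration 4, ~1000 positives at 1:1
balance) were fixed once to give the matching enough compatible ligands,
each class enough training pairs, and random pairings a low (~0.1) chance
compatibility.

What the generator does **not** imitate: real interactome degree
distributions, target-family sizes, chemical series structure, assay noise,
or database biases. Passing these suites shows the pipeline's statistics
and plumbing are sound, not that any particular accuracy will transfer to
real gold standards.

## Evaluation conventions

Accuracy, sensitivity and specificity follow the standard confusion-matrix
formulas; a rate with a zero denominator is reported missing rather than 0.
The ROC sweeps thresholds over the unique scores (ties grouped, one vertex
per unique score) from (0,0) to (1,1) and the AUC is the trapezoidal area,
which the tests verify against the Wilcoxon–Mann–Whitney rank statistic.
Cross-validated reports pool out-of-fold scores for the overall ROC (each
pair scored exactly once) and keep per-fold metrics alongside; vertical
threshold-averaging was considered and rejected as the default because
pooling is parameter-free and reproducible from the stored scores.

## Feature selection

The all-relevant selector appends a freshly permuted shadow copy of every
column per iteration, fits a permutation-importance random forest (500
trees), scores a hit when a real feature beats the best shadow, and after
`max_iter` iterations classifies each feature by a two-sided binomial test
at `alpha = 0.05`: above-chance hits are important, below-chance
unimportant, undecided tentative. "Strictly selected" features are the
important ones; "selected" adds the tentative ones. No multiplicity
correction is applied by default; alpha, iteration count and forest size
are recorded with the result.

## Known limitations

* The matched protocol's information ceiling depends on the planted
  geometry; single decision trees and linear models sit well below kernel
  and ensemble methods there, which is a statement about those model
  classes, not a defect of the data.
* MACCS key semantics follow OpenBabel's public dictionary; fingerprints
  from other dialects are accepted as bit tables but not reconciled.
* The compact BART sampler implements the standard birth/death move set;
  it is adequate for the package's problem sizes but is not a tuned
  replacement for dedicated BART packages on large problems.
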