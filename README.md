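# bowdti

Predicting protein–ligand (drug–target) interactions from a joint
"bow-pharmacological" descriptor of each candidate pair. Identifying new
interactions computationally prioritizes assays in early drug discovery,
explains off-target effects, and de-orphans phenotypic hits; `bowdti` is
aimed at computational chemists and bioinformaticians who have protein
sequences, ligand structures, and a table of known interactions, and want
calibrated interaction probabilities for new pairs.

## The descriptor and the model

Each pair (protein *p*, ligand *l*) is encoded in 439 dimensions spanning
three sub-spaces:

| sub-space | dims | content |
|---|---|---|
| protein | 107 | ten sequence feature sets: composition vector CV (20), composition moment vectors CMV¹/CMV² (40), summed physicochemical values BPC (7), neighbourhood contrasts NPC (7), index-based sequence-order correlations IPC (7), and five residue-group compositions (26) |
| ligand | 166 | MACCS structural keys (MACCSL): presence/absence of substructure patterns |
| interaction | 166 | MACCSP: the element-wise mean of the MACCS fingerprints of *p*'s known ligands |

The protein descriptors are classical sequence statistics; for example the
IPC descriptor standardizes a property scale *P* over the 20 residues and
averages lagged squared differences,

```
delta_k = (1/(N-k)) * sum_i [P(R_{i+k}) - P(R_i)]^2 ,   IPC = sum_k delta_k / (N-1),
```

so it carries sequence-order information that plain composition misses.
MACCSP injects the known interactome into the pair descriptor: a ligand
similar to a protein's known binders scores high against that protein.

Classification is by probit Bayesian additive regression trees (BART) — a
regularized sum-of-trees ensemble fitted by backfitting MCMC, implemented in
compiled code in this package — which returns a posterior-mean interaction
probability with a central 95% posterior interval per pair. Logistic
regression, an RBF-kernel SVM, a CART tree and a random forest are available
behind the same interface; probabilities above 0.5 are called interactions.

## Worked example

```r
library(bowdti)

# a self-contained synthetic gold standard with planted signal, built under
# the classical pooled protocol (entity-disjoint negative pools)
bm <- make_benchmark(pooled_benchmark_config(n_positive = 300, seed = 1))
bm
#> synthetic bow benchmark: 600 pairs (300 positive / 300 negative)
#>   100 proteins, 200 ligands, 5518 network edges, signal 0.90

dim(bm$X)
#> [1] 600 439

# train BART on the stratified 70% training portion, score the held-out 30%
model <- train_classifier(classifier_spec("bart", seed = 1),
                          bm$X[bm$split$train, ], bm$y[bm$split$train])
p <- predict_proba(model, bm$X[bm$split$test, ])
round(as.numeric(p)[1:8], 2)
#> [1] 0.37 0.66 0.76 0.61 0.72 0.75 0.34 0.71

r <- roc_auc(bm$y[bm$split$test], as.numeric(p))
m <- classification_metrics(confusion(bm$y[bm$split$test],
                                      classify(as.numeric(p))))
sprintf("AUC %.3f, accuracy %.3f, sensitivity %.3f, specificity %.3f",
        r$auc, m$accuracy, m$sensitivity, m$specificity)
#> [1] "AUC 0.994, accuracy 0.961, sensitivity 0.933, specificity 0.989"
```

Each probability is the posterior mean over 800 kept MCMC draws; the
central 95% posterior interval per pair is in `attr(p, "interval")` (the
first test pair's is [0.07, 0.75] — wide, so that call is uncertain even
though the point probability is 0.37). The AUC is the trapezoidal area
under the ROC; a probability is called an interaction only above 0.5.
Under this pooled protocol part of the performance comes from the model
recognizing entities it saw in training — the methods vignette explains
this and the leakage-free `"matched"` alternative. Real data enter through the same formats the
generator emits: a protein FASTA (`read_protein_fasta()`), a SMILES file or
pre-computed fingerprint CSV (`read_smiles()`, `read_fingerprints()`), and
a tab-separated interaction edge list (`read_edge_list()`); see
`featurize_pairs()` for assembling the 439-column matrix and
`crossval_report()` / `crossval_bow()` for stratified 10-fold evaluation
with pooled out-of-fold ROC. Shadow-feature (Boruta-style) all-relevant
feature selection is in `boruta_select()`. A command-line front end over
the same functions is in `inst/cli/bowdti.R`
(`Rscript inst/cli/bowdti.R simulate --out run1`).

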