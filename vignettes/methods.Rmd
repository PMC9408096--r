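---
title: "Predicting synaptically localized RNAs: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting synaptically localized RNAs: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synloc)
```

## The problem

Neurons transport a subset of their mRNAs out of the soma into dendrites,
where local translation supports synaptic plasticity. Which human RNAs are
dendritically (synaptically) localized is largely unknown, because clean
experimental separation of dendrites from cell bodies is hard and the
rodent studies that profiled dendritic transcriptomes agree on only a small
core of transcripts. `synloc` treats the question as an imbalanced binary
classification problem: given a brain-expressed RNA, predict the
probability that it is dendritically localized (the positive class) rather
than retained in the soma (the negative class).

Two feature families are supported:

* **Sequence features** — overlapping k-mer frequencies (k = 1, 2, 3 by
  default, 84 features) of the concatenated 5′ and 3′ UTR of the gene's
  transcript with the longest coding sequence. UTRs are the presumed
  carriers of localization elements ("zip codes").
* **Expression features** — one feature per brain sample of a
  developmental brain atlas laid out as (developmental age stage ×
  brain structure), on the `log2(RPKM + 1)` scale. Synaptic genes show
  characteristic developmental expression trajectories, which is why this
  family turns out to be the stronger predictor.

## Training-set compilation

Positive and negative instances come from several independent rodent
localization studies, mapped into human gene ID space through an ortholog
table (the mapping is many-to-many; a source gene's image is the *union*
of its human orthologs, and one-to-many expansion happens *before* overlap
counting, so a human gene supported by two studies via different source
genes still counts as two studies). The compilation rules are:

1. keep a gene only if at least `min_studies = 2` independent studies of
   the same label report it;
2. remove from the negatives anything that also appears among the
   positives (exclusion happens after ortholog mapping, in human ID space);
3. keep only genes with expression support — RPKM strictly greater than 1
   in at least 1% of brain samples, where "at least 1%" is
   `ceiling(0.01 * n_samples)` with a floor of one sample. The rounding
   convention is our choice; the boundary case (support in exactly one of
   one hundred samples) passes.

Gene identifiers are opaque strings; Ensembl-style version suffixes are
stripped on ingest because cross-source set intersection is the heart of
rule 1 and a `.5` suffix would silently break it.

## Feature encoding details

K-mer counting uses overlapping windows; windows containing `N` contribute
to no k-mer. Counts are divided by the concatenated UTR length `L` — not by
the number of windows — so for an N-free sequence the frequencies of one
`k` sum to `(L - k + 1)/L`. That denominator convention follows the
definition of the features as length-normalized counts. Sequences shorter
than the largest `k` cannot be encoded; such instances are excluded from
sequence-feature datasets and reported.

Both families are min–max scaled to `[0, 1]`. The scaler is always fitted
on training data only and applied to held-out or prediction data with
clipping into `[0, 1]`; inside cross-validation it is refitted within every
training fold. Fitting on the full data before splitting would leak
held-out information into training; the leakage-free variant is the
defensible choice wherever the alternative is unstated. A constant feature
maps to 0.

## Classifier families

Five families sit behind one train/predict contract
(`model_spec()`, `train_model()`, `predict_proba()`):

| family | backend | imbalance handling |
|---|---|---|
| `logreg` | IRLS logistic regression | case weights |
| `maxmargin` | RBF-kernel SVM (libsvm) | class weights |
| `random_forest` | probability forest (ranger) | class weights |
| `gradient_boosted_trees` | xgboost | positive-class weight |
| `ann1` | single-hidden-layer network (nnet) | bootstrap balancing |

Class weights are inversely proportional to class frequency
(`n / (2 n_c)`). The network family instead trains on a bootstrap-balanced
copy of its training data (minority class resampled with replacement up to
the majority size; when the classes are already equal the positive class is
still redrawn, keeping the procedure uniform), refreshed inside every CV
training fold.

The margin family's decision values are mapped to probabilities with a
Platt-style sigmoid fitted on out-of-fold decision values from an internal
stratified 3-fold split, so the calibration curve is never fitted on
resubstitution scores. Three folds keep the cost of the five extra fits
modest; ranking metrics (ROC-AUC) are invariant to this monotone map, so
the choice affects calibration only.

The network has exactly one hidden layer by design. Its tunables are the
hidden unit count, the weight-decay penalty and the optimizer iteration
cap (defaults 8 / 1e-3 / 100, adequate for a few hundred scaled features);
weight decay plays the regularization role that drop-out plays in
GPU-oriented frameworks, and the quasi-Newton optimizer has no learning
rate to tune. Defaults for every family live in a schema and can be
overridden per call or through the YAML config of the CLI; `grid_search()`
evaluates a Cartesian grid by stratified CV ROC-AUC with the same folds for
every point, breaking ties in favor of the first point in grid order.

All training is deterministic given the spec's seed; the RNG state of the
caller is saved and restored around every seeded operation.

## Evaluation

Threshold metrics (accuracy, sensitivity, specificity, F1, MCC) are
computed from confusion counts with the convention that a probability
**equal to** the threshold (default 0.5) is a positive call. A ratio with a
zero denominator is reported as 0 and flagged as degenerate rather than
returned as `NaN`; this keeps pooled fold means defined and is the only
convention that makes a 50-fold average robust to an occasional
single-class foldlet.

ROC-AUC is the tie-corrected rank (Mann–Whitney) statistic; PR-AUC uses
step interpolation over recall (the average-precision estimator), which
avoids the optimistic bias of trapezoids in PR space. Both are checked
against brute-force oracles in the test suite.

`repeated_cv()` runs five repetitions of stratified 10-fold
cross-validation by default. Stratification deals each class round the
folds so per-fold class counts deviate from proportionality by at most one
instance, with remainders placed on the currently smallest folds so fold
sizes also stay within one of each other. Pooled results are
means of per-fold metrics (not one metric over pooled predictions): the
mean-of-folds convention matches how per-fold feature importances are
averaged and gives every fold equal weight.

`evaluate_independent()` refuses any test instance whose ID occurred in
training — disjointness is verified, not assumed. A single-class test set
still yields threshold metrics, with the AUCs reported as `NA`.

## Feature selection

Impurity-based importances of a probability forest are collected on the
training side of every fold of a 5 × 10 CV, normalized to sum to one per
fit, and averaged over the 50 fits. `select_top()` takes the best `n`
(ties lexicographic). For expression features,
`aggregate_by_sample_metadata()` averages importances of all samples
sharing a (developmental stage, tissue) cell into a grid whose rows and
columns are sorted by descending marginal importance — the standard way to
visualize which developmental windows and brain structures carry the
signal. Features with exactly-zero mean importance are treated as unscored
and excluded from cell means. Samples are weighted equally within a cell
(not by cell size); permutation importance is available as an alternative
to impurity importance in `ranger` but is not the default, since
impurity importances are the convention the original modeling stack used.

## Candidate prioritization and enrichment

Three trained models (canonically the margin, forest and network families)
score the brain-expressed candidate list. A gene is a **consensus**
(high-confidence) candidate only when all three probabilities reach the
threshold; the final ranking is by arithmetic mean probability, ties broken
by gene ID so the ranking is total and reproducible.

Enrichment of a reference gene set (e.g. a curated synaptic-gene
catalogue) near the top of the ranking uses a weighted
Kolmogorov–Smirnov-style running sum: walking down the ranking, set members
add `|score|^p / sum_set |score|^p` (default `p = 1`) and non-members
subtract `1/(N - n_set)`; the enrichment score is the signed deviation of
maximum magnitude, and the running sum returns to zero at the end of the
list. The null distribution permutes set membership — random gene sets of
identical size — which is the standard preranked surrogate for
phenotype-label permutation (the latter needs per-sample data the
preranked setting does not have). The nominal p-value is the fraction of
same-sign null scores at least as extreme, with a plus-one correction so
it can never be exactly zero: with 1000 permutations the smallest
reportable value is about 0.001.

## The synthetic study conditions

`sim_config()` defines the conditions under which the pipeline is
exercised and accepted, with no external downloads:

* 300 positive and 300 negative genes;
* a 200-sample expression grid — 5 brain structures × 8 developmental
  stages × 5 samples per cell — with log-normal RPKM marginals
  (`2^Normal(2, 1)`), so the RPKM > 1 support filter genuinely bites on
  low-expression genes;
* class signal planted on the 20 samples of the 4 earliest (stage,
  structure) blocks as a +2 shift of mean log2 expression in positives,
  mirroring the early-development cortical blocks that importance grids
  recover from real atlases; with effect size 0 the classes are
  exchangeable by construction;
* UTRs of 100–400 nt, i.i.d. uniform bases, optionally with named k-mers
  emitted several-fold more often in positive-class sequences;
* three pseudo-studies per label with a configurable overlap fraction, a
  partly many-to-many ortholog map, decoy source IDs with no mapping, and
  ground-truth bookkeeping of exactly which genes were planted into at
  least two studies.

What the generator does *not* imitate matters for interpretation: real
developmental atlases have strong gene–gene and sample–sample correlation,
batch structure, and heavy-tailed expression; real UTR composition is far
from i.i.d. Passing the planted-signal tests therefore demonstrates that
the pipeline's machinery is correct and calibrated — not that any
particular real-data accuracy will be reached.

## Numerical and degenerate-input choices

* Probabilities exactly at the decision threshold are positive calls.
* Zero-denominator metrics are flagged zeros, never `NaN`.
* Constant features min–max-scale to 0; out-of-range values clip to
  `[0, 1]` and are counted.
* Enrichment errors on set–list disjointness and on zero total hit weight;
  the all-hits degenerate set scores exactly 1 at the last position; a tie
  in magnitude between the largest positive and largest negative running-sum
  deviation resolves to the positive one (within 1e-12), so the score's
  sign never depends on floating-point accumulation order.
* TSV writers serialize doubles with 17 significant digits so matrices
  round-trip bit-identically.
* All stochastic steps take explicit integer seeds; the CLI fans one
  global seed out to per-stage seeds through a fixed per-subcommand
  offset, so any stage can be re-run alone and reproduce its in-pipeline
  output bit for bit (manifests record the seed, parameter hash and input
  checksums of every run).

## Problem sizes used by the bundled checks

The test suite and `scripts/acceptance.R` run the planted-signal
conditions above: five repetitions of 10-fold CV for the margin, forest
and network families on the 600 × 200 study; 50 re-simulated zero-effect
studies scored with single-repetition 10-fold CV for the null-calibration
band; importance over all 50 folds with 300-tree forests; 500
running-sum oracle comparisons and 500 null-calibration enrichment trials
at 199 permutations; and a reduced end-to-end run (60 + 80 genes, 48
samples) executed twice to verify bit-identical outputs. These sizes are
the package's chosen study conditions; raising them only tightens the same
checks.

## Known limitations

* The bundled conditions are synthetic; applying the package to a real
  atlas requires the user to supply localization lists, an ortholog table,
  UTR FASTA and the expression matrix in the documented formats.
* The margin family's probabilities are only as good as a two-parameter
  sigmoid on decision values; isotonic or beta calibration is out of scope.
* No FDR control across multiple gene sets — the enrichment interface
  tests one set at a time.
* Sequence features are plain k-mer frequencies; secondary structure,
  positional and motif features are deliberately out of scope.
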