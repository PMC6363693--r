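---
title: "Consensus fingerprint QSAR for sweetener classification and relative sweetness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus fingerprint QSAR for sweetener classification and relative sweetness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

Two prediction tasks drive this package. The first is binary: given a small
organic molecule, is it a sweetener or a non-sweetener? The second is
continuous: for a sweetener, what is its relative sweetness (RS) — its
sweetness intensity relative to a 5% w/v sucrose reference — modeled on the
log10 scale, `y = log10(RS)`. Both tasks use only the 2D molecular graph:
sweet-tasting compounds tend to be conformationally flexible, so
conformation-dependent 3D descriptors make predictions irreproducible, and
circular fingerprints on the heavy-atom graph are the descriptor of choice.

The methodological core is a *consensus protocol*: rather than trusting a
single train/test split and a single learner, the same dataset is split many
times, a grid of models is trained per split, models are averaged over
splits, and small named ensembles ("consensus models") serve predictions by
averaging constituent outputs. The package follows the OECD QSAR
principles: a defined endpoint, an unambiguous and fully seeded algorithm, a
defined applicability domain, internal (cross-validation), external
(hold-out) and robustness (Y-randomization) statistics, and fingerprint-bit
interpretation.

## The fingerprint engine

`ecfp()` implements extended-connectivity fingerprints natively so that
every set bit carries provenance back to the substructure that produced it.

* **Initial invariants.** Each heavy atom is hashed from the tuple (atomic
  number, heavy-neighbor count, attached-H count, formal charge, in-ring
  flag, aromatic flag). Ring membership is computed by cycle detection
  (an atom is in a ring iff it touches a non-bridge edge); aromaticity is
  taken from file annotation (`ar` bonds in MOL2, bond type 4 in SDF) — the
  package performs no independent aromaticity perception.
* **Iteration.** For `r = 1..radius` each atom's identifier is rehashed
  from `(r, own id, sorted (bond code, neighbor id) pairs)` with bond codes
  single = 1, double = 2, triple = 3, aromatic = 4. ECFP4 is radius 2,
  ECFP6 radius 3 (the suffix is the diameter).
* **Hashing.** 32-bit FNV-1a over the little-endian serialization of the
  integer tuple. The choice is deliberate: deterministic, portable,
  dependency-free, and cheap. Bit-exact agreement with any other ECFP
  implementation is therefore *not* expected — different engines use
  different hashes — but similarity *structure* is preserved, which is what
  QSAR consumes. The test suite checks rank agreement of pairwise Tanimoto
  matrices against an independent reference implementation (Spearman
  > 0.9 on 50 random molecules).
* **Deduplication.** Environments covering an atom set already covered by
  an earlier environment are discarded; "earlier" means the smaller
  (iteration, identifier) pair, which fixes the tie-break the original
  algorithm description leaves open.
* **Folding.** Retained identifiers map to bit `(id mod n_bits) + 1`
  (1-based, as is natural in R) with `n_bits` 1024 or 2048. Collisions are
  visible in the provenance: `bit_substructure()` returns every environment
  folded onto a bit.

Explicit hydrogens in input files are collapsed into per-heavy-atom
attached-H counts before fingerprinting; MOL2 formal charges are read as 0
because the Tripos charge column holds partial charges, while SDF `M  CHG`
lines are honored.

## Datasets, curation and splitting

`curate_compounds()` applies four rules in order: keep the largest fragment
of disconnected structures (ties: larger summed atomic mass, then lowest
original atom index); keep only compounds made of C, H, O, N, S, P, Si, F,
Cl, Br, I; for classification drop *all* copies of a structure annotated
with conflicting taste labels; deduplicate identical structures across
sources keeping the first. Structure identity uses the cheap key (molecular
formula, 2048-bit ECFP6 bit string). Regression records must be referenced
to 5% w/v sucrose and have RS > 0.

Two splitting schemes mirror the two tasks:

* `split_classification()` samples 80% of each class (round half up)
  without replacement into Dataset-CV; the rest is Dataset-Test. The scheme
  id doubles as the RNG seed, so scheme `s` is reproducible everywhere.
* `split_regression()` sorts by `y` (ties by id), cuts consecutive blocks
  of five (final partial block included), and draws one compound per block
  into Dataset-Test — an evenly y-stratified hold-out. A 352-compound
  dataset yields 71 test / 281 CV compounds; the final-partial-block rule is
  what reproduces those counts.

The full protocol repeats the split 19 times for KNN, SVM, GBM and RF and
3 times for the networks (DNN2/DNN3), whose training cost is much higher.

## The model grid

`enumerate_grid()` crosses four fingerprints (ECFP4/ECFP6 at 1024/2048
bits), four feature options (full, top512, top256, top128), six method
labels (KNN, SVM, GBM, RF, DNN2, DNN3) and the per-method scheme counts:
1312 models, of which 328 use full features and 984 use feature subsets.
Feature subsets come from `rank_features()`: one random forest per
(fingerprint, scheme) pair — 76 runs — whose impurity-based importance
vectors are averaged and ranked descending (ties to the lower bit index),
making top128 a prefix of top256 a prefix of top512.

`train_cv()` runs stratified five-fold cross-validation over Dataset-CV for
every hyperparameter assignment, selects the best mean fold F1-score
(classification) or R² (regression, ties to the first assignment in grid
order), refits on all of Dataset-CV, and records the cross-validated
metrics; `evaluate_test()` attaches hold-out metrics. If a fold misses a
class, stratification is retried with the next seed (five attempts).

Hyperparameter grids are documented, configurable defaults
(`default_grids()`): KNN `k ∈ {1,3,5,7,9}` under Jaccard (1 − Tanimoto) distance;
SVM (RBF) `C ∈ {0.1,1,10,100}`, `γ ∈ {1/p, 0.01, 0.001}`; RF
`ntree ∈ {100,500}` with `mtry = √p`; GBM `nrounds ∈ {100,300}`,
`η ∈ {0.05,0.1}`, depth `∈ {3,5}`; DNN2 hidden (1024, 512) and DNN3 hidden
(1024, 512, 256), ReLU, dropout 0.25, Adam (learning rate 1e-3), binary
cross-entropy / MSE loss, early stopping on an internal 10% validation
slice, at most 200 epochs. `reduced_grids()` is a pruned search for quick
runs and examples.

Every classifier exposes a positive-class score in [0, 1], which the
consensus layer requires. The SVM score deserves a note: the libsvm
probability machinery uses an internal random cross-validation that is not
reproducible from R's RNG, so the package fits its own Platt-style sigmoid
(`glm` of the labels on the decision values) — a deterministic calibration.
The networks are a compact multilayer perceptron implemented directly in
matrix code (ReLU hidden layers, inverted dropout, Adam, early stopping);
at fingerprint dimensionalities and dataset sizes of a few hundred to a few
thousand compounds this is fast and fully seeded.

## Average and consensus models

`build_average_models()` groups trained models by (fingerprint, feature
option, method) and averages every metric over schemes — 96 groups for the
full grid; a group missing a scheme is an error, and undefined metrics are
excluded from averaging with a warning rather than silently propagating
NaN. The named consensus models are:

| name | constituents | count (full protocol) |
|------|--------------|----------------------|
| CM01 | per-scheme best individual model, networks excluded | 19 |
| CM02 | per-scheme best individual model, networks included | 19 |
| CM03 | top average models by the selection metric | 5 |
| CM04 | best average model per method family (DNN2/DNN3 pooled) | 5 |

Regression defines CM01–CM03 only. Selection uses F1 (classification) or
R² (regression); by default constituents are ranked on their
*cross-validated* metric (`select_on = "cv"`), because ranking on test
metrics would leak the hold-out set into model selection — the design was
genuinely open here, and `select_on = "test"` is available for comparison.
Prediction averages constituent outputs with equal weights (an
average-model constituent contributes the mean over its per-scheme
members): the mean positive-class probability with threshold 0.5 (an exact
0.5 maps to "sweet") or the mean log10 RS, also reported back-transformed
as `RS = 10^mean`. Score averaging subsumes majority voting and is
deterministic. Cross-scheme metric summaries are t-based 95% confidence
intervals, `mean ± t(0.975, n−1)·sd/√n` (`confidence_interval()`);
`bland_altman()` provides the limits-of-agreement machinery used to compare
against external models.

## Applicability domain

A prediction is trusted only inside the model's chemical neighborhood:
`average_similarity()` retrieves the query's five nearest Dataset-CV
compounds by Tanimoto similarity on 2048-bit ECFP6 and averages the five
similarities. The compound is in-domain iff that average is *strictly*
greater than the threshold, default 0.1 — an average of exactly 0.1 is
outside. When a CV compound scores its own partition it is excluded from
its own neighbor list, since a guaranteed self-similarity of 1 would
inflate the histogram. The threshold is a configuration value: 0.1 is a
reading of where average-similarity histograms (`ad_histogram()`, bin
width 0.05) separate in-distribution from alien chemistry, not the output
of a quantitative rule, so it must remain tunable.

## Y-randomization

`y_randomize()` shuffles the Dataset-CV responses (permutation seeded by
the scheme id), reruns the identical training protocol, and evaluates on
the true, unshuffled test responses. A model that learned genuine
structure–taste relationships collapses toward chance; a model that merely
memorized noise does not. The identity permutation is accepted as a
control and reproduces the unshuffled run exactly. One caveat the package's
own experiments make visible: the *per-scheme* shuffled-label test MCC is a
noisy quantity — its sampling scale is roughly `1/√n_test`, and chance
correlation between the shuffled labels and a strongly informative
substructure is amplified by the learner — so individual schemes can stray
a few tenths from zero even though the collapse (shuffled metric well below
the real metric, in every scheme) is robust.

## The synthetic data generator

Curated taste datasets are not freely redistributable, so the package
generates its own study material.
`generate_molecules()` grows random connected heavy-atom trees under common
organic valences (C 4, N 3, O 2, S 2, P 3, Si 4, halogens 1), closes one
ring with probability 0.3, and fills remaining valence with hydrogens; all
bonds are single. `plant_labels()` embeds small distinctive motifs
(fragments carrying Cl, S or P, elements absent from the default C/N/O
alphabet) and derives the response from motif presence:

* classification — one motif, embedded with probability 0.5; the label is
  flipped with noise rate ε (default 0.05, dataset size 400);
* regression — three motifs with effects (1, 0.7, 0.5) on log10 RS plus an
  intercept 0.3 and Gaussian noise σ (default 0.1, dataset size 352, the
  curated RS dataset's size).

These defaults are the package's fixed study conditions: ε = 0.05 keeps the
Bayes F1 near 0.95 so that pipeline recovery (consensus test F1 ≥ 0.9,
test R² ≥ 0.8) is a meaningful bar, and n = 352 exercises the 71/281
stratified split at its documented size. What the generator emulates is the
*pipeline contract* — structure files in, planted structure–response
signal, recoverable by fingerprint models. What it does not emulate:
realistic chemistry (no aromatic systems, no charged species, no tautomers),
realistic property distributions, label noise that correlates with
structure, or the class imbalance and scaffold clustering of curated taste
datasets. Passing the planted-recovery tests therefore demonstrates that
the machinery is correct and unbiased, not that any particular real-world
accuracy will be achieved.

## Numerical choices and degenerate inputs

* Undefined metrics (zero denominators) are `NA` markers, never NaN; they
  are excluded from averages and confidence intervals with a warning.
* All tie-breaks are documented and deterministic: fragment selection
  (atoms, mass, index), feature ranking (lower bit), hyperparameter search
  (first in grid order), nearest neighbors (lower reference index),
  consensus threshold (0.5 maps to sweet).
* Tanimoto of two all-zero fingerprints is 0 by convention.
* Every random step is seeded from scheme ids or explicit seeds, so reruns
  are bit-identical; learner seeds are derived as documented in
  `train_cv()`.
* Empty molecules, empty datasets, empty manifests, inconsistent structure
  files and infeasible valence requests raise immediate errors.

## Problem sizes used by the tests

The test suite runs the full protocol's combinatorics symbolically (grid
counts, 96 average-model groups) but trains models at reduced scale chosen
to keep the suite comfortably interactive: one fingerprint (ECFP4-1024),
two feature options, the KNN/RF (classification) or RF/GBM (regression)
families, three splitting schemes, and the `reduced_grids()` search, on the
default planted datasets (400 / 352 compounds). The brute-force metric
oracle enumerates all ~10,600 confusion tables with at most 20 compounds.
The fingerprint oracle compares 1,225 compound pairs against an independent
reference implementation.

## Known limitations

* No aromaticity perception: file annotation is trusted. Structures from
  sources with Kekulé-only encodings will fingerprint differently from
  aromatic-annotated copies of the same molecule.
* MOL2 formal charges are not recovered (partial-charge column); use SDF
  with `M  CHG` when charges matter.
* The regression applicability domain inherits the training set's limited
  chemical diversity; RS extrapolation outside it is flagged, not refused.
* Hyperparameter defaults are documented stand-ins for unpublished
  originals; users wanting to mirror a specific setup should edit
  `default_grids()`.
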