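---
title: "Predicting metabolic roles of receptors from co-expression modules"
author: "MetReceptor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting metabolic roles of receptors from co-expression modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

MetReceptor rests on a single biological assumption: receptors that
participate in a tissue's metabolic programme are co-expressed with that
programme's genes. Under this assumption, the functional signature of a
receptor is not its own expression profile but the *pathway profile of its
co-expression module*, which is far more robust to single-gene noise and
reduces the feature dimension from thousands of genes to a few hundred
pathways. The pipeline turns this into a supervised problem in five
stages: preprocess, build the network and modules, score modules against
pathways, expand a small positive seed set by positive-unlabeled (PU)
learning, and classify.

## Preprocessing

Expression values are assumed to be on a log2 scale. Where raw-scale
thresholds apply (the "0.1 in 80% of samples" filter), the log transform
is inverted as `raw = 2^x - 1`; the pseudocount of 1 is the package's
convention (it keeps zeros finite) and both base and pseudocount are
arguments of `filterGenes()` for data transformed differently.

Outlier samples are scored by *standardized connectivity*: the mean
correlation of a sample with all other samples, z-scored, with samples
below −3 removed. The sample-network literature offers several distance
choices; mean inter-sample correlation is the package default and a
Euclidean variant is available via `metric = "euclidean"`. When the
connectivity scores have zero variance (all samples identical) no sample
is an outlier.

Known-factor adjustment is a per-gene location-scale correction applied
iteratively, one categorical factor at a time, in the order batch →
ischemic-time bin → sex → age decade: within each factor level a gene is
centred to its grand mean and rescaled to the pooled within-level standard
deviation, so later factors see data already corrected for earlier ones.
This removes additive and multiplicative known-factor effects exactly in
the synthetic regime and preserves each gene's grand mean to numerical
precision; it deliberately omits empirical-Bayes shrinkage of the
per-level estimates, which matters only when levels contain very few
samples. Hidden-confounder removal by principal components is deliberately
absent: in heterogeneous tissue panels it removes genuine co-expression
signal, which is the very signal this method classifies. Ischemic time is
binned into five 300-minute intervals (capped), age into decades, and only
the ventilator death-class group is analysed by default, the group with
the shortest ischemic times and best-preserved expression.

## Network and modules

The co-expression measure is the biweight midcorrelation, which
downweights values far from the median and is therefore robust to the
occasional extreme sample; genes with zero median absolute deviation fall
back to Pearson deviations (the standard convention), and exactly
constant genes are rejected upstream. The signed adjacency
`a_ij = (0.5 (1 + cor))^beta` with `beta = 12` maps correlation into
[0, 1] so that anticorrelated genes receive near-zero adjacency — modules
are sets of *positively* co-regulated genes. The power 12 is the
conventional signed-network default; `scaleFreeFit()` reports the
log-log degree fit R² as a diagnostic but the power is never changed
automatically, keeping runs comparable.

Topological overlap (TOM) rewards shared neighbourhoods over single
edges, and modules are cut from an average-linkage tree of `1 - TOM`.
The package uses a *static* cut (default height 0.995) with a minimum
module size of 30 and iterative merging of modules whose eigengenes
correlate above 0.75 (merge height 0.25). A dynamic, variable-height
tree cut can find modules in harder topologies, but it is
parameter-opaque; the static cut is deterministic, fully
parameter-explicit, and recovers planted modules essentially perfectly
in the regimes the tests cover. Labels are renumbered by decreasing
size, so "module 1" is always the largest module; genes in no module
carry label 0 and are excluded from all downstream receptor analysis.

Module eigengenes are unit-normalized first principal components of the
gene-standardized module submatrix, sign-oriented so they track the mean
member profile; `kME(g, m)` is the correlation of gene g with eigengene
m.

## Enrichment features

Each module is tested against each pathway by the one-sided
hypergeometric (Fisher exact upper-tail) test — the standard
over-representation statistic. P-values are Benjamini–Hochberg adjusted
*within each module across its pathways*, matching how per-list
enrichment tools adjust. The universe defaults to all module-assigned
genes and is recorded in the output (`attr(, "universe_size")`) because
p-values depend on it; passing all expressed genes is supported. A
receptor's feature row is its module's `-log10(p_adj)` vector with
non-significant entries (p_adj ≥ 0.05) zeroed first, so the feature
space is exactly the thresholded enrichment heatmap. Two receptors in
one module therefore have identical rows by construction — the method
classifies *module context*, not individual profiles.

## PU label expansion

With few known positives and no negatives, `puBagging()` runs t = 100
rounds; each round treats a bootstrap of k unlabeled points (k defaults
to the number of seed positives) as provisional negatives, trains a
linear SVM with fixed cost 1, and records a binary vote on each
out-of-bag point. The out-of-bag "score" is read as the classification
vote, which is what a rate over 100 experiments naturally aggregates; a
margin-based variant (logistic-squashed decision values) sits behind
`scoreType = "margin"`. Rates built on fewer than 10 out-of-bag
appearances are reported as undefined rather than thresholded, so one or
two lucky votes can never label a receptor. Candidates with positive rate
> 0.7 become positives only if they pass an *accept list* — the
package's reproducible stand-in for manual literature and ontology
verification; `acceptList = "all"` yields the algorithm's raw expansion.
Receptors with negative rate `1 - rate > 0.8` become inferred negatives.
An externally supplied cytokine-receptor list forms the second,
independent negative group and takes precedence over inference so that
both negative groups stay populated and disjoint.

## Classification and evaluation

Both final classifiers work on the enrichment feature space: a linear
SVM with cost tuned over `2^(-5..5)` (ties to the smallest cost, the
larger-margin preference) and a k-NN with Euclidean distance, k chosen
as the *largest* value in 1..10 attaining the minimal cross-validation
error. Hyperparameters are tuned once globally rather than nested within
each fold — with tens of labeled receptors, nesting leaves training
folds too small; the possible optimistic bias is acknowledged and a
nested option would be the first extension. k-NN is implemented in the
package rather than delegated, because deterministic tie-breaking is
required for reproducible runs: distance ties resolve to the smallest
training index and even-k vote ties resolve to the negative class,
the conservative choice that minimizes false positives (the error mode
this application cares about). The test suite cross-checks it against a
reference k-NN on tie-free data.

Evaluation is 10-fold unstratified random cross-validation (stratification
available), folds reseeded until every training set contains both
classes, with confusion counts summed over test folds. `computeMetrics()`
offers two variants. The `"paper"` variant reproduces the reference
literature's reported table: sensitivity `TP/(TP+FN)` and specificity
`TN/(TN+FN)`. That specificity is *not* the textbook definition — but it
is the only reading that reproduces the published table's numbers, whose
printed sensitivity formula `TP/(TP+FP)` conversely does not reproduce
its own table. The `"standard"` variant provides the textbook
`TN/(TN+FP)`. Accuracy and MCC are standard in both variants; metrics
with zero denominators are reported as undefined. Consensus prediction
intersects the positive calls of the four final models (SVM/k-NN × two
negative groups), recording the per-receptor vote vector so near-misses
(3 of 4) remain visible.

## The synthetic generator

`simulateReceptorData()` emulates exactly the statistical structure the
method assumes: one standard-normal latent factor per module and sample,
member genes loading on it with strength `moduleSignal` against Gaussian
noise (`noiseSd`), additive per-gene-per-batch shifts, uniformly drawn
per-gene means, uncorrelated background genes, pathways drawn at
`pathwayPurity` from their target modules, metabolic receptors planted in
module 1, non-metabolic receptors spread over the other modules (module
2's doubling as the cytokine-list analogue) and background, and a seed
positive subset of one third of the metabolic receptors — chosen so that
label expansion has real work to do, mirroring a seed list much smaller
than the eventual positive set. Under this model the within-module
correlation is approximately `signal² / (signal² + noise²)`, which the
generator tests verify empirically.

The standard study conditions used throughout the tests and the
acceptance script are 600 genes, three modules of 100, 60 receptors (40%
metabolic), loading 1.5 against unit noise, two batches with shift SD
0.5, 15 pathways of 10–50 genes at purity 0.8, and generator seed 7. The
generated cohort has 160 samples with 75% in the ventilator death class,
so at least 100 samples survive the death-class subset — comfortably
above the sample size where module detection is reliable, while keeping
the full suite fast at desk scale. For the consensus stage, the
acceptance analysis withholds a quarter of the non-seed planted metabolic
receptors from the accept list, emulating true metabolic receptors absent
from the literature; these are precisely the receptors the four-model
consensus should rediscover.

What the generator does *not* emulate: read counts or RPKM computation
(values are simulated directly on the log2 scale), realistic covariate
distributions or covariate-expression coupling beyond batch, overlapping
or nested pathways, and correlated module factors. Passing tests
therefore demonstrate that the implementation recovers the structure the
method assumes when that structure is present — not that real tissue
data satisfies those assumptions. One synthetic-regime artifact is worth
knowing: with planted modules occupying a large fraction of all genes,
quantile normalization couples background genes weakly (and negatively)
to the module factors, since forcing each sample's value distribution to
a common reference makes large coordinated module shifts push the
remaining genes the other way. At the transcriptome scale this effect is
negligible; in the 600-gene fixture it measurably inflates background
kME, which is why the kME unit tests use a batch-free fixture.

## Numerical choices and degenerate inputs

Determinism is a contract throughout: every stochastic step (generator,
bagging, folds) takes an explicit seed, and rerunning the pipeline with
identical inputs and configuration produces byte-identical outputs, with
provenance (parameters, seeds, input hashes) written alongside. Other
conventions: bicor medians and MADs use the midpoint convention for
ties; eigengene sign is fixed by non-negative correlation with the mean
member profile; empty networks yield zero TOM off-diagonal; a cut
producing no module of minimum size warns and leaves all genes
unassigned; singleton factor levels are removed before adjustment and
single-level factors are skipped with a warning; an empty unlabeled set
yields an empty consensus. Tolerances asserted in the tests are 1e-12
for closed-form identities (adjacency poles, TOM oracle, BH step-up,
MCC-phi equivalence) and 1e-9 for grand-mean preservation under batch
adjustment.

## Limitations

The static tree cut will fragment or miss modules in topologies that
need variable-height cutting; module counts are parameter-dependent and
never treated as a target. Location-scale adjustment assumes known,
categorical confounders. The accept-list mechanism makes the human
verification step explicit and reproducible but cannot substitute for
it. And because features are shared within modules, the classifiers
cannot distinguish receptors inside one module — finer resolution would
require gene-level features such as kME profiles, a natural extension.
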