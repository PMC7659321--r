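# MetReceptor

Predicting tissue-specific metabolic roles of receptor genes from bulk
expression data.

Receptors transduce inter-organ signalling: ligands secreted by source
organs bind receptors on target tissues, closing the feedback loops that
maintain metabolic homeostasis. For most receptors the tissue-specific
function is unknown, and databases offer no "metabolic receptor"
annotation. MetReceptor implements a guilt-by-association strategy for
this problem, aimed at computational biologists working with cohort-scale
RNA-seq (GTEx-style tissue panels): receptors that act in a tissue's
metabolic programme tend to be co-expressed with metabolic genes, so the
pathway profile of a receptor's co-expression module is a learnable
signature of metabolic function.

## Method

1. **Preprocessing** — expression filtering (raw value ≥ 0.1 in ≥ 80% of
   samples), removal of samples whose standardized connectivity z-score is
   below −3, quantile normalization, and iterative per-gene location-scale
   adjustment for known factors (experimental batch, ischemic-time bin,
   sex, age decade), restricted to the ventilator death-class group.
2. **Signed weighted co-expression network** — biweight midcorrelation
   `bicor(i,j)`, signed soft-threshold adjacency

   `a_ij = (0.5 · (1 + cor(i,j)))^β`,  β = 12,

   topological overlap `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 − a_ij)`
   with `l_ij = Σ_u a_iu a_uj`, average-linkage clustering of `1 − TOM`,
   size-filtered static cut, eigengene merging, and module membership
   `kME(g,m) = cor(x_g, ME_m)` where `ME_m` is the module's first
   principal component.
3. **Feature space** — each module is scored against a pathway collection
   by the one-sided hypergeometric test with Benjamini–Hochberg adjustment;
   a receptor's feature vector is its module's `−log10(p_adj)` profile
   (zeroed where `p_adj ≥ 0.05`).
4. **PU label expansion** — positive-unlabeled bagging: each of t = 100
   rounds trains a linear SVM of the seed positives against k bootstrapped
   unlabeled points and votes on the out-of-bag points; receptors with
   positive rate > 0.7 (and passing an accept list standing in for
   literature verification) become positives, receptors with negative rate
   > 0.8 become inferred negatives.
5. **Classification and consensus** — linear SVM (tuned cost) and k-NN
   (largest k in 1..10 with minimal error) evaluated by 10-fold
   cross-validation with sensitivity, specificity, accuracy and the
   Matthews correlation coefficient; novel metabolic receptors are the
   unlabeled receptors predicted positive by all four models
   (2 classifiers × 2 negative groups).

A synthetic-data generator (`simulateReceptorData`) plants known
co-expression modules, batch effects, pathway annotations and a labeled
receptor subset, so the whole pipeline is testable against ground truth.

## Worked example

```r
library(MetReceptor)

## simulate a small cohort with two planted co-expression modules
cfg <- syntheticConfig(nGenes = 200, nSamples = 120,
                       moduleSizes = c(60L, 60L), nReceptors = 24,
                       nPathways = 8, rngSeed = 3)
dat <- simulateReceptorData(cfg)

## preprocess and detect modules on the signed network
se <- preprocessExpression(dat$se)$se
adj <- softAdjacency(bicorMatrix(se), beta = 12, signed = TRUE)
partition <- detectModules(tomSimilarity(adj), se)
partition
#> ModulePartition: 198 genes, 2 modules, 80 unassigned
#>   module sizes: 60, 58

## pathway enrichment -> receptor feature space
enr <- enrichModules(partition, dat$pathways)
features <- buildFeatureMatrix(partition, enr, dat$receptors)
features
#> ReceptorFeatures: 17 receptors x 6 pathways; 7 receptors excluded

## expand labels from the positive seed set by PU bagging
seedPos <- intersect(dat$seedPositives, rownames(featureValues(features)))
rates <- puBagging(features, seedPos, t = 100, rngSeed = 11)
labels <- deriveLabels(rates, seedPositives = seedPos,
                       cytokineReceptors = dat$cytokineReceptors)
labels
#> LabelSet: 10 positive, 0 inferred-negative, 7 cytokine-negative, 0 unlabeled

## cross-validate a final classifier
ld <- labeledData(features, labels, negatives = "cytokine")
counts <- crossValidate(ld$x, ld$y, "knn", k = 3, rngSeed = 11)
counts
#> ConfusionCounts: TP = 10 TN = 7 FP = 0 FN = 0
unlist(computeMetrics(counts)$rounded)
#> sensitivity specificity    accuracy         mcc
#>           1           1           1           1
```

The module partition recovers the two planted modules (background genes
stay unassigned), the receptors inherit their module's enrichment profile,
PU bagging promotes the planted metabolic receptors to positives, and the
k-NN classifier separates them from the cytokine-style negatives without
error on this clean fixture. `runPipeline()` performs the same stages from
files on disk and writes every stage output plus a provenance record.

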