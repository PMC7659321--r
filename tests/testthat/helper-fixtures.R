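## Shared fixtures, built once per test run.
##
## standardFixture(): the package's standard synthetic study conditions
## (600 genes, 3 planted modules of 100, 160 generated samples, 60
## receptors, module loading 1.5 vs unit noise, generator seed 7) carried
## through preprocessing, network construction, module detection,
## enrichment, the receptor feature space and PU bagging.

fixtureCache <- new.env(parent = emptyenv())

.exprsOf <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1L) else x
}

standardFixture <- function() {
  if (!is.null(fixtureCache$std)) return(fixtureCache$std)
  dat <- simulateReceptorData(syntheticConfig(rngSeed = 7))
  pp <- preprocessExpression(dat$se)
  se <- pp$se
  cc <- bicorMatrix(se)
  tom <- tomSimilarity(softAdjacency(cc))
  partition <- detectModules(tom, se)
  enr <- suppressWarnings(enrichModules(partition, dat$pathways))
  features <- suppressMessages(
    buildFeatureMatrix(partition, enr, dat$receptors))
  seedAvail <- intersect(dat$seedPositives,
                         rownames(featureValues(features)))
  rates <- puBagging(features, seedAvail, rngSeed = 101)
  fixtureCache$std <- list(dat = dat, se = se, cc = cc, tom = tom,
                           partition = partition, enr = enr,
                           features = features, seedAvail = seedAvail,
                           rates = rates)
  fixtureCache$std
}

## map each detected module label to the planted module its members
## majority-belong to
detectedToTruth <- function(partition, truth) {
  mem <- moduleMembership(partition)
  tm <- truth$moduleOfGene[names(mem)]
  labs <- sort(unique(mem[mem > 0L]))
  vapply(labs, function(l) {
    tt <- table(tm[mem == l])
    as.integer(names(tt)[which.max(tt)])
  }, integer(1))
}

## linearly separable two-class toy set in 2 dimensions
separableData <- function(n = 20, gap = 10, seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n), ncol = 2),
             matrix(rnorm(n, mean = gap), ncol = 2))
  rownames(x) <- sprintf("r%02d", seq_len(nrow(x)))
  colnames(x) <- c("f1", "f2")
  y <- setNames(factor(rep(c("neg", "pos"), each = n / 2),
                       levels = c("neg", "pos")), rownames(x))
  list(x = x, y = y)
}
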