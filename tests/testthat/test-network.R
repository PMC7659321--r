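## scalar biweight midcorrelation computed directly from the defining
## formula, independent of the matrix code path
bicorScalar <- function(x, y) {
  dev <- function(v) {
    med <- median(v); madv <- mad(v, constant = 1)
    if (madv == 0) return(v - mean(v))
    u <- (v - med) / (9 * madv)
    (v - med) * (1 - u^2)^2 * (abs(u) < 1)
  }
  dx <- dev(x); dy <- dev(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

test_that("bicor: self-correlation and monotone affine pairs give 1", {
  set.seed(2)
  x <- rnorm(10)
  m <- rbind(a = x, b = 2 * x + 3)
  cc <- bicorMatrix(m)
  expect_equal(diag(cc), c(a = 1, b = 1))
  expect_equal(cc["a", "b"], 1, tolerance = 1e-12)
})

test_that("bicor downweights a gross outlier relative to Pearson", {
  x <- 1:10
  y <- c(1:9, 1000)
  m <- rbind(x = x, y = y)
  b <- bicorMatrix(m)["x", "y"]
  p <- cor(x, y)
  expect_gt(b, p)
  expect_equal(b, bicorScalar(x, y), tolerance = 1e-12)
})

test_that("bicor agrees with the defining formula on random pairs", {
  set.seed(7)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    expect_equal(bicorMatrix(rbind(x, y))["x", "y"], bicorScalar(x, y),
                 tolerance = 1e-12)
  }
})

test_that("zero-MAD genes fall back to Pearson", {
  x <- c(5, 5, 5, 5, 5, 5, 1, 9, 2, 8)   # median-heavy: MAD = 0
  y <- c(2, 2, 2, 2, 2, 2, 7, 0, 6, 1)
  expect_equal(mad(x, constant = 1), 0)
  expect_equal(bicorMatrix(rbind(x = x, y = y))["x", "y"], cor(x, y),
               tolerance = 1e-12)
  expect_error(bicorMatrix(rbind(a = rep(1, 6), b = rnorm(6))),
               "constant gene")
})

test_that("signed soft adjacency matches its closed form at the poles", {
  cc <- matrix(c(1, -1, 0, -1, 1, 0.5, 0, 0.5, 1), 3, 3)
  a <- softAdjacency(cc, beta = 12, signed = TRUE)
  expect_equal(a[1, 1], 1, tolerance = 1e-12)
  expect_equal(a[1, 2], 0, tolerance = 1e-12)
  expect_equal(a[1, 3], 0.5^12, tolerance = 1e-12)
  ## unsigned variant
  expect_equal(softAdjacency(cc, 2, signed = FALSE)[1, 2], 1)
})

test_that("soft adjacency is monotone in correlation and in beta", {
  cors <- seq(-1, 1, by = 0.05)
  a12 <- softAdjacency(cors, beta = 12)
  expect_true(all(diff(a12) > 0))
  a6 <- softAdjacency(cors, beta = 6)
  inner <- cors > -1 & cors < 1
  expect_true(all(a12[inner] < a6[inner]))
  expect_error(softAdjacency(cors, beta = 0.5))
})

test_that("TOM matches hand values on degenerate networks", {
  ones <- matrix(1, 3, 3)
  tom <- tomSimilarity(ones)
  expect_equal(tom[1, 2], (1 + 1) / (2 + 1 - 1), tolerance = 1e-12)
  zeros <- diag(3)
  tz <- tomSimilarity(zeros)
  expect_true(all(tz[upper.tri(tz)] == 0))
  expect_equal(diag(tz), rep(1, 3))
})

test_that("TOM agrees with a triple-loop oracle on random networks", {
  set.seed(11)
  tomOracle <- function(a) {
    n <- nrow(a); diag(a) <- 0
    out <- diag(n)
    for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
      l <- 0
      for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      out[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    out
  }
  for (rep in 1:100) {
    a <- matrix(runif(36), 6, 6)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_lt(max(abs(tomSimilarity(a) - tomOracle(a))), 1e-12)
  }
})

test_that("TOM output is symmetric and bounded for arbitrary input", {
  set.seed(12)
  a <- matrix(runif(100), 10, 10); a <- (a + t(a)) / 2; diag(a) <- 1
  tom <- tomSimilarity(a)
  expect_equal(tom, t(tom))
  expect_true(all(tom >= 0 & tom <= 1))
})

test_that("module detection recovers the planted partition", {
  fx <- standardFixture()
  mem <- moduleMembership(fx$partition)
  truth <- fx$dat$truth$moduleOfGene[names(mem)]
  ari <- mclust::adjustedRandIndex(mem, truth)
  expect_gt(ari, 0.9)
  ## planted metabolic receptors co-locate in one detected module
  met <- intersect(fx$dat$truth$metabolicReceptors, names(mem))
  shares <- table(mem[met])
  expect_gte(max(shares) / length(met), 0.9)
})

test_that("module size and merge thresholds behave as documented", {
  fx <- standardFixture()
  expect_warning(huge <- detectModules(fx$tom, fx$se,
                                       minModuleSize = 1e5),
                 "unassigned")
  expect_true(all(moduleMembership(huge) == 0L))
  noMerge <- detectModules(fx$tom, fx$se, mergeHeight = 0)
  mem <- moduleMembership(noMerge)
  labs <- sort(unique(mem[mem > 0L]))
  expect_identical(labs, seq_along(labs))   # contiguous labels
  ## module 1 is the largest
  expect_equal(which.max(tabulate(mem[mem > 0L])), 1L)
})

test_that("eigengene is the oriented first principal component", {
  set.seed(3)
  profile <- rnorm(30)
  m <- t(sapply(1:5, function(i) 2 * profile + rnorm(30, sd = 1e-3)))
  dimnames(m) <- list(sprintf("g%d", 1:5), sprintf("s%d", 1:30))
  me <- moduleEigengene(m)
  expect_equal(sum(me^2), 1, tolerance = 1e-12)
  expect_gt(abs(cor(me, profile)), 0.999)
  expect_gte(cor(me, rowMeans(scale(t(m)))), 0)
  ## negating every member flips the eigengene to track the negated mean
  meNeg <- moduleEigengene(-m)
  expect_gt(cor(meNeg, -profile), 0.999)
  ## single-gene module: the gene's standardized unit profile
  one <- moduleEigengene(m[1, , drop = FALSE])
  expect_equal(abs(cor(one, profile)), 1, tolerance = 1e-6)
})

test_that("eigengenes of the planted modules track their latent factors", {
  fx <- standardFixture()
  x <- SummarizedExperiment::assay(fx$dat$se)
  truth <- fx$dat$truth
  for (m in sort(unique(truth$moduleOfGene[truth$moduleOfGene > 0L]))) {
    members <- names(which(truth$moduleOfGene == m))
    me <- moduleEigengene(x, members)
    expect_gt(abs(cor(me, truth$factors[m, ])), 0.95)
  }
})

test_that("kME is bounded and small for background genes", {
  ## pure latent-factor regime (no batch structure) at large n
  cfg <- syntheticConfig(nGenes = 300, nSamples = 200,
                         moduleSizes = c(60L, 60L), nReceptors = 20,
                         nBatches = 1, ventilatorFrac = 1, rngSeed = 13)
  dat <- simulateReceptorData(cfg)
  x <- SummarizedExperiment::assay(dat$se)
  cc <- bicorMatrix(x)
  part <- detectModules(tomSimilarity(softAdjacency(cc)), x)
  kme <- moduleKME(part)
  expect_true(all(abs(kme) <= 1 + 1e-12))
  bg <- intersect(names(which(dat$truth$moduleOfGene == 0L)),
                  rownames(kme))
  expect_lt(max(abs(kme[bg, ])), 0.3)
  ## the module core follows its own eigengene closely (a handful of
  ## absorbed background genes may not)
  mem <- moduleMembership(part)
  own <- kme[cbind(which(mem == 1L), 1L)]
  expect_gt(median(own), 0.7)
  ## kmeMatrix is the correlation with the eigengenes by definition
  expect_equal(kmeMatrix(x, part), kme, tolerance = 1e-12)
})
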