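test_that("deterministic k-NN matches class::knn when there are no ties", {
  set.seed(19)
  sep <- separableData(40)
  idx <- sample(40, 30)
  train <- sep$x[idx, ]; test <- sep$x[-idx, ]
  cl <- sep$y[idx]
  for (k in c(1, 3, 5)) {
    mine <- MetReceptor:::.knnClassify(train, test, cl, k)
    ref <- class::knn(train, test, cl, k)
    expect_identical(as.character(mine), as.character(ref))
  }
})

test_that("k-NN breaks even-k vote ties toward the negative class", {
  train <- matrix(c(0, 0, 1, 1), 2, 2,
                  dimnames = list(c("n", "p"), c("f1", "f2")))
  cl <- factor(c("neg", "pos"), levels = c("neg", "pos"))
  test <- matrix(0.5, 1, 2, dimnames = list("q", c("f1", "f2")))
  expect_identical(as.character(
    MetReceptor:::.knnClassify(train, test, cl, 2)), "neg")
})

test_that("neighbour-count selection returns the largest k at minimal error", {
  sep <- separableData(40)
  k <- selectKnnK(sep$x, sep$y, kGrid = 1:10, rngSeed = 5)
  errs <- attr(k, "errors")
  expect_equal(unname(errs), rep(0, 10))   # separable: every k is perfect
  expect_equal(as.numeric(k), 10)          # all tied -> maximal k
  ## two tight positives inside a negative neighbourhood: k = 1..2 perfect,
  ## larger k swallows them -> rule picks 2, the largest minimiser
  x <- cbind(f1 = c(0, 0.1, 5, 5.1, 5.2, 5.3, 5.4, 5.5), f2 = 0)
  rownames(x) <- sprintf("r%d", 1:8)
  y <- setNames(factor(c("pos", "pos", rep("neg", 6)),
                       levels = c("neg", "pos")), rownames(x))
  k2 <- selectKnnK(x, y, kGrid = 1:4, nFolds = 4, rngSeed = 3)
  errs2 <- attr(k2, "errors")
  expect_equal(as.numeric(k2), max(which(errs2 <= min(errs2) + 1e-12)))
  expect_error(selectKnnK(x, y, kGrid = integer(0)), "empty")
})

test_that("cost tuning minimizes CV error with ties to the smallest cost", {
  sep <- separableData(40)
  grid <- 2^(-5:5)
  cost <- tuneSvmCost(sep$x, sep$y, grid, rngSeed = 5)
  expect_equal(as.numeric(cost), 2^-5)     # separable: all tie, smallest
  ## oracle: independent exhaustive sweep with the same folds
  set.seed(23)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2),
             matrix(rnorm(40, 1.2), ncol = 2))
  rownames(x) <- sprintf("r%02d", 1:40)
  y <- setNames(factor(rep(c("neg", "pos"), each = 20),
                       levels = c("neg", "pos")), rownames(x))
  cost2 <- tuneSvmCost(x, y, grid, rngSeed = 7)
  folds <- MetReceptor:::.makeFolds(y, 10, 7)
  sweep <- vapply(grid, function(cc) {
    wrong <- 0
    for (f in 1:10) {
      fit <- e1071::svm(x[folds != f, ], y[folds != f], kernel = "linear",
                        cost = cc, scale = FALSE)
      wrong <- wrong + sum(predict(fit, x[folds == f, ]) != y[folds == f])
    }
    wrong / length(y)
  }, numeric(1))
  expect_equal(min(sweep), unname(attr(cost2, "errors")[as.character(cost2)]))
  expect_equal(as.numeric(cost2), min(grid[sweep <= min(sweep) + 1e-12]))
  expect_error(tuneSvmCost(x, y, numeric(0)), "empty")
})

test_that("cross-validation conserves class totals and is deterministic", {
  sep <- separableData(40)
  nPos <- sum(sep$y == "pos"); nNeg <- sum(sep$y == "neg")
  for (seed in 1:5) {
    cnt <- crossValidate(sep$x, sep$y, "knn", k = 3, rngSeed = seed)
    v <- confusionVector(cnt)
    expect_equal(unname(v["tp"] + v["fn"]), nPos)
    expect_equal(unname(v["tn"] + v["fp"]), nNeg)
  }
  ## perfectly separated data: no misclassifications
  cnt <- crossValidate(sep$x, sep$y, "knn", k = 1, rngSeed = 1)
  expect_equal(unname(confusionVector(cnt)[c("fp", "fn")]), c(0L, 0L))
  expect_length(cnt@fpIds, 0)
  a <- crossValidate(sep$x, sep$y, "svm", cost = 1, rngSeed = 4)
  b <- crossValidate(sep$x, sep$y, "svm", cost = 1, rngSeed = 4)
  expect_identical(confusionVector(a), confusionVector(b))
})

test_that("metrics reproduce the reference table from printed counts", {
  rows <- list(
    list(c(tp = 50, tn = 55, fp = 0, fn = 2),
         c(sensitivity = 0.96, specificity = 0.96, accuracy = 0.98,
           mcc = 0.96)),
    list(c(tp = 44, tn = 55, fp = 0, fn = 8),
         c(sensitivity = 0.85, specificity = 0.87, accuracy = 0.93,
           mcc = 0.86)),
    list(c(tp = 42, tn = 60, fp = 1, fn = 10),
         c(sensitivity = 0.81, specificity = 0.86, accuracy = 0.9,
           mcc = 0.81)))
  for (row in rows) {
    m <- computeMetrics(row[[1]], variant = "paper")
    expect_equal(m$rounded, row[[2]])
  }
})

test_that("metric variants, degenerate counts and errors behave correctly", {
  m <- computeMetrics(c(tp = 1, tn = 1, fp = 1, fn = 1))
  expect_equal(m$mcc, 0)
  ## standard specificity uses TN/(TN+FP); paper variant TN/(TN+FN)
  std <- computeMetrics(c(tp = 50, tn = 55, fp = 0, fn = 2), "standard")
  expect_equal(std$specificity, 1)
  pap <- computeMetrics(c(tp = 50, tn = 55, fp = 0, fn = 2), "paper")
  expect_equal(pap$specificity, 55 / 57)
  ## zero denominators are undefined, not errors
  z <- computeMetrics(c(tp = 0, tn = 5, fp = 0, fn = 0))
  expect_true(is.na(z$sensitivity))
  expect_error(computeMetrics(c(tp = -1, tn = 1, fp = 1, fn = 1)),
               "negative")
})

test_that("MCC equals the Pearson phi of the binary vectors", {
  for (tp in 0:5) for (tn in 0:5) for (fp in 0:5) for (fn in 0:5) {
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) next
    y <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
    pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
    m <- computeMetrics(c(tp = tp, tn = tn, fp = fp, fn = fn))
    expect_equal(m$mcc, cor(y, pred), tolerance = 1e-12)
  }
})

test_that("consensus requires a positive vote from every model", {
  train1 <- matrix(c(0, 0), 1, 2,
                   dimnames = list("p", c("f1", "f2")))
  posModel <- structure(list(method = "knn", train = train1,
                             y = factor("pos", levels = c("neg", "pos")),
                             k = 1), class = "recClassifier")
  negModel <- structure(list(method = "knn", train = train1,
                             y = factor("neg", levels = c("neg", "pos")),
                             k = 1), class = "recClassifier")
  newx <- matrix(c(1, 1), 1, 2, dimnames = list("u1", c("f1", "f2")))
  res <- consensusPredict(newx, list(posModel, posModel, posModel,
                                     negModel))
  expect_length(res$consensus, 0)
  expect_equal(sum(res$votes["u1", ]), 3)
  all4 <- consensusPredict(newx, rep(list(posModel), 4))
  expect_identical(all4$consensus, "u1")
  empty <- consensusPredict(newx[0, , drop = FALSE], list(posModel))
  expect_length(empty$consensus, 0)
  expect_error(consensusPredict(newx, list(posModel, "no")), "trained")
})

test_that("SVM and k-NN classify the planted receptor classes accurately", {
  fx <- standardFixture()
  labels <- deriveLabels(fx$rates, seedPositives = fx$seedAvail,
                         cytokineReceptors = fx$dat$cytokineReceptors)
  ld <- labeledData(fx$features, labels, "inferred")
  for (method in c("svm", "knn")) {
    cnt <- crossValidate(ld$x, ld$y, method, cost = 1, k = 3, rngSeed = 5)
    acc <- computeMetrics(cnt)$accuracy
    expect_gte(acc, 0.9)
  }
})
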