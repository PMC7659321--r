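## deterministic k-nearest-neighbour classifier (Euclidean distance):
## distance ties broken by smallest training index, even-k vote ties toward
## the negative class (conservative, minimizes false positives)
.knnClassify <- function(train, test, cl, k) {
  stopifnot(k >= 1, nrow(train) >= k)
  cl <- factor(cl, levels = c("neg", "pos"))
  pred <- apply(test, 1, function(p) {
    d <- sqrt(colSums((t(train) - p)^2))
    nn <- order(d, seq_along(d))[seq_len(k)]
    if (sum(cl[nn] == "pos") > k / 2) "pos" else "neg"
  })
  factor(pred, levels = c("neg", "pos"))
}

#' Extract the labeled design matrix for one negative group
#'
#' @param features a \code{\link{ReceptorFeatures-class}}.
#' @param labels a \code{\link{LabelSet-class}}.
#' @param negatives which negative group to use.
#' @return list with matrix \code{x} and factor \code{y} (levels
#'   \code{neg}, \code{pos}) named by receptor.
#' @export
labeledData <- function(features, labels,
                        negatives = c("inferred", "cytokine")) {
  negatives <- match.arg(negatives)
  sets <- labelSets(labels)
  neg <- if (negatives == "inferred") sets$negativesInferred
         else sets$negativesCytokine
  x <- featureValues(features)
  pos <- intersect(sets$positives, rownames(x))
  neg <- intersect(neg, rownames(x))
  if (!length(pos) || !length(neg))
    stop("both classes must be present in the feature matrix")
  ids <- c(pos, neg)
  list(x = x[ids, , drop = FALSE],
       y = setNames(factor(rep(c("pos", "neg"), c(length(pos), length(neg))),
                           levels = c("neg", "pos")), ids))
}

## random unstratified fold assignment; refolds (with an incremented seed,
## logged) until every training set contains both classes
.makeFolds <- function(y, nFolds, rngSeed) {
  n <- length(y)
  for (try in 0:99) {
    set.seed(rngSeed + try)
    folds <- sample(rep_len(seq_len(nFolds), n))
    ok <- all(vapply(seq_len(nFolds), function(f)
      length(unique(y[folds != f])) == 2L, logical(1)))
    if (ok) {
      if (try > 0) message(sprintf("refolded %d time(s) to keep both classes in every training set", try))
      return(folds)
    }
  }
  stop("could not build folds with both classes in every training set")
}

#' Fit a final classifier on all labeled data
#'
#' @param x labeled feature matrix.
#' @param y factor with levels \code{neg}, \code{pos}.
#' @param method \code{"svm"} (linear kernel) or \code{"knn"}.
#' @param cost SVM cost (method \code{"svm"}).
#' @param k neighbour count (method \code{"knn"}).
#' @return a fitted classifier usable with \code{\link{predictClassifier}}.
#' @export
fitClassifier <- function(x, y, method = c("svm", "knn"), cost = 1, k = 1) {
  method <- match.arg(method)
  y <- factor(y, levels = c("neg", "pos"))
  obj <- if (method == "svm")
    list(method = "svm",
         fit = e1071::svm(x, y, kernel = "linear", cost = cost,
                          scale = FALSE))
  else list(method = "knn", train = x, y = y, k = k)
  structure(obj, class = "recClassifier")
}

#' Predict with a fitted classifier
#'
#' @param model a \code{\link{fitClassifier}} result.
#' @param newx matrix of feature rows to classify.
#' @return factor of predictions with levels \code{neg}, \code{pos}.
#' @export
predictClassifier <- function(model, newx) {
  if (!inherits(model, "recClassifier")) stop("model is not trained")
  if (model$method == "svm") predict(model$fit, newx)
  else .knnClassify(model$train, newx, model$y, model$k)
}

## CV error rate for one classifier specification
.cvError <- function(x, y, folds, method, cost = 1, k = 1) {
  wrong <- 0L
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- fitClassifier(x[tr, , drop = FALSE], y[tr], method,
                           cost = cost, k = k)
    pred <- predictClassifier(model, x[!tr, , drop = FALSE])
    wrong <- wrong + sum(pred != y[!tr])
  }
  wrong / length(y)
}

#' Select the k-NN neighbour count
#'
#' Evaluates the cross-validation error rate for each candidate k and
#' returns the \emph{largest} k attaining the minimal error (so the
#' smoothest classifier among the best performers; with all errors equal
#' this is the maximal grid value).
#'
#' @param x,y labeled data as from \code{\link{labeledData}}.
#' @param kGrid candidate neighbour counts, default 1..10.
#' @param nFolds CV folds, default 10.
#' @param rngSeed fold seed.
#' @return the selected k; attribute \code{"errors"} carries the grid.
#' @export
selectKnnK <- function(x, y, kGrid = 1:10, nFolds = 10, rngSeed = 1L) {
  if (!length(kGrid)) stop("empty k grid")
  folds <- .makeFolds(y, nFolds, rngSeed)
  errs <- vapply(kGrid, function(k) .cvError(x, y, folds, "knn", k = k),
                 numeric(1))
  best <- max(kGrid[errs <= min(errs) + 1e-12])
  structure(best, errors = setNames(errs, kGrid))
}

#' Tune the linear-SVM cost
#'
#' Evaluates the cross-validation error over the cost grid and returns the
#' cost minimizing it; ties go to the \emph{smallest} cost (maximal-margin
#' preference).
#'
#' @param x,y labeled data.
#' @param costGrid candidate costs, default \code{2^(-5:5)}.
#' @param nFolds CV folds.
#' @param rngSeed fold seed.
#' @return the selected cost; attribute \code{"errors"} carries the grid.
#' @export
tuneSvmCost <- function(x, y, costGrid = 2^(-5:5), nFolds = 10,
                        rngSeed = 1L) {
  if (!length(costGrid)) stop("empty cost grid")
  if (length(unique(y)) < 2) stop("both classes required for tuning")
  folds <- .makeFolds(y, nFolds, rngSeed)
  errs <- vapply(costGrid, function(cc)
    .cvError(x, y, folds, "svm", cost = cc), numeric(1))
  best <- min(costGrid[errs <= min(errs) + 1e-12])
  structure(best, errors = setNames(errs, costGrid))
}

#' Cross-validate a classifier and sum confusion counts
#'
#' Random unstratified partition into \code{nFolds} folds; each fold is
#' classified by a model trained on the rest and the true/false
#' positive/negative counts are summed over the test folds.
#'
#' @param x,y labeled data (y levels \code{neg}, \code{pos}, named by
#'   receptor).
#' @param method \code{"svm"} or \code{"knn"}.
#' @param cost,k hyperparameters for the respective method.
#' @param nFolds folds, default 10.
#' @param rngSeed fold seed; results are deterministic given it.
#' @return a \code{\link{ConfusionCounts-class}} with misclassified ids.
#' @export
crossValidate <- function(x, y, method = c("svm", "knn"), cost = 1, k = 1,
                          nFolds = 10, rngSeed = 1L) {
  method <- match.arg(method)
  y <- setNames(factor(y, levels = c("neg", "pos")), names(y))
  folds <- .makeFolds(y, nFolds, rngSeed)
  pred <- y
  for (f in sort(unique(folds))) {
    tr <- folds != f
    model <- fitClassifier(x[tr, , drop = FALSE], y[tr], method,
                           cost = cost, k = k)
    pred[!tr] <- predictClassifier(model, x[!tr, , drop = FALSE])
  }
  ids <- names(y)
  methods::new("ConfusionCounts",
               tp = sum(pred == "pos" & y == "pos"),
               tn = sum(pred == "neg" & y == "neg"),
               fp = sum(pred == "pos" & y == "neg"),
               fn = sum(pred == "neg" & y == "pos"),
               fpIds = ids[pred == "pos" & y == "neg"],
               fnIds = ids[pred == "neg" & y == "pos"])
}

#' Performance metrics from confusion counts
#'
#' Computes sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient. \code{variant = "paper"} uses the forms that reproduce the
#' reference result table: sensitivity \eqn{TP/(TP+FN)} and specificity
#' \eqn{TN/(TN+FN)}; \code{variant = "standard"} uses the textbook
#' specificity \eqn{TN/(TN+FP)}. Accuracy is \eqn{(TP+TN)/(TP+FP+TN+FN)}
#' and \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#' {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' A metric with a zero denominator is reported as \code{NA} (undefined).
#'
#' @param counts a \code{\link{ConfusionCounts-class}} or named vector with
#'   entries \code{tp}, \code{tn}, \code{fp}, \code{fn}.
#' @param variant metric variant, see above.
#' @param digits rounding applied to the \code{rounded} element for report
#'   parity (default 2).
#' @return list with the unrounded metrics, a \code{rounded} vector, the
#'   variant, and the misclassified-id lists when available.
#' @export
computeMetrics <- function(counts, variant = c("paper", "standard"),
                           digits = 2) {
  variant <- match.arg(variant)
  v <- if (methods::is(counts, "ConfusionCounts")) confusionVector(counts)
       else counts[c("tp", "tn", "fp", "fn")]
  if (any(v < 0)) stop("negative counts")
  tp <- as.numeric(v["tp"]); tn <- as.numeric(v["tn"])
  fp <- as.numeric(v["fp"]); fn <- as.numeric(v["fn"])
  safe <- function(num, den) if (den == 0) NA_real_ else num / den
  sens <- safe(tp, tp + fn)
  spec <- if (variant == "paper") safe(tn, tn + fn) else safe(tn, tn + fp)
  acc <- safe(tp + tn, tp + fp + tn + fn)
  mccDen <- sqrt((tp + fp) * (tp + fn)) * sqrt((tn + fp) * (tn + fn))
  mcc <- if (mccDen == 0) NA_real_ else (tp * tn - fp * fn) / mccDen
  out <- list(sensitivity = sens, specificity = spec, accuracy = acc,
              mcc = mcc, variant = variant,
              rounded = round(c(sensitivity = sens, specificity = spec,
                                accuracy = acc, mcc = mcc), digits))
  if (methods::is(counts, "ConfusionCounts")) {
    out$fpIds <- counts@fpIds
    out$fnIds <- counts@fnIds
  }
  out
}

#' Consensus prediction over four final models
#'
#' Classifies unlabeled receptors with each supplied model (canonically the
#' four combinations of SVM/k-NN with the two negative groups) and returns
#' the receptors predicted positive by \emph{every} model, together with
#' the per-receptor vote matrix.
#'
#' @param newx feature rows of the unlabeled receptors (may be empty).
#' @param models list of trained \code{\link{fitClassifier}} objects.
#' @return list with \code{consensus} (ids positive under all models) and
#'   \code{votes} (receptors x models logical matrix).
#' @export
consensusPredict <- function(newx, models) {
  if (!length(models) || !all(vapply(models, inherits, logical(1),
                                     "recClassifier")))
    stop("all models must be trained classifiers")
  if (!nrow(newx))
    return(list(consensus = character(),
                votes = matrix(logical(), 0, length(models))))
  votes <- vapply(models, function(m)
    predictClassifier(m, newx) == "pos", logical(nrow(newx)))
  votes <- matrix(votes, nrow = nrow(newx),
                  dimnames = list(rownames(newx),
                                  names(models) %||% seq_along(models)))
  list(consensus = rownames(newx)[rowSums(votes) == length(models)],
       votes = votes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
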