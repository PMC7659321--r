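#' Positive-unlabeled bagging with linear SVMs
#'
#' Expands supervision from a small positive seed set: each round draws a
#' bootstrap sample of \code{k} unlabeled points (with replacement, over
#' points rather than ids) as provisional negatives, trains a linear SVM of
#' positives versus that sample, and classifies the out-of-bag (OOB)
#' unlabeled points. A point's positive rate is the fraction of its OOB
#' appearances in which it was classified positive; rates backed by fewer
#' than \code{minOOB} appearances are reported as \code{NA}.
#'
#' @param features a \code{\link{ReceptorFeatures-class}} or a numeric
#'   matrix with receptor row names.
#' @param seedPositives ids of the known positives (>= 2).
#' @param unlabeled ids of the unlabeled points; defaults to every feature
#'   row not in \code{seedPositives}.
#' @param t number of bagging iterations, default 100.
#' @param k bootstrap sample size; defaults to \code{length(seedPositives)}.
#' @param cost linear-SVM cost, fixed (default 1) inside bagging.
#' @param minOOB minimum OOB appearances for a defined rate, default 10.
#' @param scoreType \code{"vote"} records the binary classification (the
#'   default reading of the OOB score); \code{"margin"} records the SVM
#'   decision value squashed through a logistic link.
#' @param rngSeed seed making the whole procedure deterministic.
#' @return a \code{\link{PURates-class}} object.
#' @export
puBagging <- function(features, seedPositives, unlabeled = NULL, t = 100L,
                      k = NULL, cost = 1, minOOB = 10L,
                      scoreType = c("vote", "margin"), rngSeed = 1L) {
  scoreType <- match.arg(scoreType)
  x <- if (methods::is(features, "ReceptorFeatures"))
    featureValues(features) else as.matrix(features)
  stopifnot(t >= 1L)
  if (length(seedPositives) < 2) stop("need at least 2 seed positives")
  if (!all(seedPositives %in% rownames(x)))
    stop("seed positives missing from the feature matrix")
  if (is.null(unlabeled)) unlabeled <- setdiff(rownames(x), seedPositives)
  if (!length(unlabeled)) stop("no unlabeled points")
  if (is.null(k)) k <- length(seedPositives)
  xp <- x[seedPositives, , drop = FALSE]
  xu <- x[unlabeled, , drop = FALSE]
  nu <- length(unlabeled)
  set.seed(rngSeed)
  score <- numeric(nu)
  appearances <- integer(nu)
  y <- factor(c(rep("pos", nrow(xp)), rep("neg", k)),
              levels = c("neg", "pos"))
  for (iter in seq_len(t)) {
    idx <- sample.int(nu, k, replace = TRUE)
    oob <- setdiff(seq_len(nu), idx)
    fit <- e1071::svm(rbind(xp, xu[idx, , drop = FALSE]), y,
                      kernel = "linear", cost = cost, scale = FALSE)
    if (!length(oob)) next
    if (scoreType == "vote") {
      pred <- predict(fit, xu[oob, , drop = FALSE])
      score[oob] <- score[oob] + (pred == "pos")
    } else {
      pr <- predict(fit, xu[oob, , drop = FALSE], decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      ## libsvm orients decision values by the first class seen in training
      dvv <- if (colnames(dv)[1] == "neg/pos") -dv[, 1] else dv[, 1]
      score[oob] <- score[oob] + 1 / (1 + exp(-dvv))
    }
    appearances[oob] <- appearances[oob] + 1L
  }
  rate <- ifelse(appearances >= minOOB, score / pmax(appearances, 1L),
                 NA_real_)
  if (all(is.na(rate)))
    warning("no unlabeled point reached the minimum OOB appearances; ",
            "all rates undefined")
  methods::new("PURates", receptor = unlabeled,
               oobCount = appearances, positiveRate = as.numeric(rate),
               t = as.integer(t), k = as.integer(k),
               minOOB = as.integer(minOOB))
}

#' Derive receptor labels from PU rates
#'
#' Thresholds the out-of-bag positive rates: candidates with rate above
#' \code{posThreshold} become positives if they are on the accept list (the
#' reproducible stand-in for manual literature/GO verification; candidates
#' failing it stay unlabeled and are reported as pending); points whose
#' negative rate \code{1 - rate} exceeds \code{negThreshold} become inferred
#' negatives. The cytokine negative list is kept disjoint from both.
#'
#' @param rates a \code{\link{PURates-class}} object.
#' @param posThreshold positive-rate threshold in (0.5, 1], default 0.7.
#' @param negThreshold negative-rate threshold in (0.5, 1], default 0.8.
#' @param acceptList ids accepted by external verification, or \code{"all"}
#'   to accept every candidate (the algorithm's raw expansion).
#' @param seedPositives ids of the original seed positives, kept positive.
#' @param cytokineReceptors independent cytokine-style negative list.
#' @return a \code{\link{LabelSet-class}}; attribute \code{"pending"} lists
#'   candidates awaiting verification.
#' @export
deriveLabels <- function(rates, posThreshold = 0.7, negThreshold = 0.8,
                         acceptList = "all", seedPositives = character(),
                         cytokineReceptors = character()) {
  stopifnot(posThreshold > 0.5, posThreshold <= 1,
            negThreshold > 0.5, negThreshold <= 1)
  df <- puRates(rates)
  defined <- !is.na(df$positiveRate)
  candidates <- df$receptor[defined & df$positiveRate > posThreshold]
  accepted <- if (identical(acceptList, "all")) candidates
              else intersect(candidates, acceptList)
  pending <- setdiff(candidates, accepted)
  positives <- union(seedPositives, accepted)
  cytokine <- setdiff(cytokineReceptors, positives)
  negInferred <- setdiff(
    df$receptor[defined & (1 - df$positiveRate) > negThreshold],
    c(positives, cytokine))
  unlabeled <- setdiff(unique(df$receptor),
                       c(positives, negInferred, cytokine))
  out <- methods::new("LabelSet", positives = sort(positives),
                      negativesInferred = sort(negInferred),
                      negativesCytokine = sort(cytokine),
                      unlabeled = sort(unlabeled))
  attr(out, "pending") <- sort(pending)
  out
}
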