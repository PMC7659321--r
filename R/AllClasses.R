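#' @import methods
#' @importFrom stats cor sd median mad phyper p.adjust hclust cutree as.dist
#'   prcomp quantile rnorm runif setNames var aggregate
#' @importFrom utils read.delim write.table head
NULL

#' Gene-to-module partition with eigengenes and module membership
#'
#' Result of co-expression module detection. Module labels are positive
#' integers numbered by decreasing module size (module 1 is the largest);
#' label 0 marks genes not assigned to any module.
#'
#' @slot membership named integer vector, gene -> module label (0 =
#'   unassigned).
#' @slot eigengenes samples x modules numeric matrix of module eigengenes
#'   (unit-normalised first-principal-component scores), columns named
#'   \code{"ME<label>"}.
#' @slot kME genes x modules numeric matrix of module membership values,
#'   i.e. the correlation of each gene's profile with each module eigengene.
#'
#' @export
setClass("ModulePartition", representation(
  membership = "integer",
  eigengenes = "matrix",
  kME = "matrix"
))

setValidity("ModulePartition", function(object) {
  msg <- character()
  m <- object@membership
  if (is.null(names(m))) msg <- c(msg, "membership must be named by gene id")
  if (any(m < 0L)) msg <- c(msg, "module labels must be >= 0")
  labs <- sort(unique(m[m > 0L]))
  if (length(labs) && !identical(labs, seq_along(labs)))
    msg <- c(msg, "module labels must be contiguous from 1")
  if (ncol(object@eigengenes) != length(labs))
    msg <- c(msg, "one eigengene column per module required")
  if (nrow(object@kME) && any(abs(object@kME) > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "kME values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Receptor feature matrix of module pathway-enrichment scores
#'
#' Rows are receptors, columns pathways; the value is the
#' \eqn{-\log_{10}}(adjusted p) enrichment score of the receptor's module for
#' that pathway when significant, else 0. Receptors in the same module have
#' identical rows by construction; receptors outside any module are absent.
#'
#' @slot values receptors x pathways numeric matrix of scores (>= 0).
#' @slot moduleOf named integer vector mapping each receptor row to the
#'   module that supplied its scores.
#' @slot excluded character vector of receptor ids dropped because they were
#'   unassigned (module 0) or absent from the expression data.
#'
#' @export
setClass("ReceptorFeatures", representation(
  values = "matrix",
  moduleOf = "integer",
  excluded = "character"
))

setValidity("ReceptorFeatures", function(object) {
  msg <- character()
  if (any(object@values < 0)) msg <- c(msg, "scores must be non-negative")
  if (!identical(rownames(object@values), names(object@moduleOf)))
    msg <- c(msg, "moduleOf must be named to match feature rows")
  if (any(object@moduleOf == 0L))
    msg <- c(msg, "module-0 receptors must not appear in the feature matrix")
  if (length(msg)) msg else TRUE
})

#' Receptor label sets for positive-unlabeled classification
#'
#' Supervision state of the receptor universe: known positives (metabolic),
#' two variants of negatives (inferred by PU bagging, and an independent
#' cytokine-receptor list), and the remaining unlabeled receptors.
#'
#' @slot positives character vector of positive (metabolic) receptor ids.
#' @slot negativesInferred character vector of PU-inferred strong negatives.
#' @slot negativesCytokine character vector of cytokine-list negatives.
#' @slot unlabeled character vector of receptors with no label.
#'
#' @export
setClass("LabelSet", representation(
  positives = "character",
  negativesInferred = "character",
  negativesCytokine = "character",
  unlabeled = "character"
))

setValidity("LabelSet", function(object) {
  sets <- list(object@positives, object@negativesInferred,
               object@negativesCytokine, object@unlabeled)
  n <- sum(lengths(sets))
  if (length(unique(unlist(sets))) != n)
    "label sets must be pairwise disjoint" else TRUE
})

#' Out-of-bag positive rates from PU bagging
#'
#' Per-receptor aggregation of out-of-bag (OOB) votes over the bagging
#' rounds: \code{positiveRate} is the fraction of OOB appearances in which
#' the round's SVM classified the receptor as positive. Rates with fewer
#' than \code{minOOB} appearances are reported as \code{NA} (undefined).
#'
#' @slot receptor character vector of unlabeled receptor ids.
#' @slot oobCount integer vector, number of OOB appearances per receptor.
#' @slot positiveRate numeric vector in [0, 1] (or NA when undefined).
#' @slot t number of bagging iterations.
#' @slot k bootstrap sample size per iteration.
#' @slot minOOB minimum OOB appearances for a defined rate.
#'
#' @export
setClass("PURates", representation(
  receptor = "character",
  oobCount = "integer",
  positiveRate = "numeric",
  t = "integer",
  k = "integer",
  minOOB = "integer"
))

setValidity("PURates", function(object) {
  msg <- character()
  if (length(object@receptor) != length(object@oobCount) ||
      length(object@receptor) != length(object@positiveRate))
    msg <- c(msg, "receptor, oobCount and positiveRate lengths must match")
  ok <- !is.na(object@positiveRate)
  if (any(object@positiveRate[ok] < 0 | object@positiveRate[ok] > 1))
    msg <- c(msg, "positiveRate must lie in [0, 1]")
  if (any(object@oobCount > object@t))
    msg <- c(msg, "oobCount cannot exceed the number of iterations")
  if (length(msg)) msg else TRUE
})

#' Confusion counts summed over cross-validation test folds
#'
#' @slot tp,tn,fp,fn non-negative integer counts of true positives, true
#'   negatives, false positives and false negatives.
#' @slot fpIds,fnIds ids of the misclassified receptors (false positives and
#'   false negatives).
#'
#' @export
setClass("ConfusionCounts", representation(
  tp = "integer", tn = "integer", fp = "integer", fn = "integer",
  fpIds = "character", fnIds = "character"
))

setValidity("ConfusionCounts", function(object) {
  if (any(c(object@tp, object@tn, object@fp, object@fn) < 0L))
    "counts must be non-negative" else TRUE
})

setMethod("show", "ModulePartition", function(object) {
  m <- object@membership
  nm <- sum(tabulate(m[m > 0L]) > 0)
  cat("ModulePartition:", length(m), "genes,", nm, "modules,",
      sum(m == 0L), "unassigned\n")
  if (nm) {
    sz <- table(factor(m[m > 0L]))
    cat("  module sizes:", paste(sz, collapse = ", "), "\n")
  }
})

setMethod("show", "ReceptorFeatures", function(object) {
  cat("ReceptorFeatures:", nrow(object@values), "receptors x",
      ncol(object@values), "pathways;",
      length(object@excluded), "receptors excluded\n")
})

setMethod("show", "LabelSet", function(object) {
  cat("LabelSet:", length(object@positives), "positive,",
      length(object@negativesInferred), "inferred-negative,",
      length(object@negativesCytokine), "cytokine-negative,",
      length(object@unlabeled), "unlabeled\n")
})

setMethod("show", "PURates", function(object) {
  def <- !is.na(object@positiveRate)
  cat("PURates: t =", object@t, ", k =", object@k, ";",
      length(object@receptor), "receptors (", sum(def), "defined rates )\n")
})

setMethod("show", "ConfusionCounts", function(object) {
  cat("ConfusionCounts: TP =", object@tp, "TN =", object@tn,
      "FP =", object@fp, "FN =", object@fn, "\n")
})

#' @describeIn ModulePartition-class gene -> module label vector.
#' @param object a \code{ModulePartition}.
#' @export
setGeneric("moduleMembership", function(object)
  standardGeneric("moduleMembership"))
setMethod("moduleMembership", "ModulePartition", function(object)
  object@membership)

#' @describeIn ModulePartition-class samples x modules eigengene matrix.
#' @export
setGeneric("moduleEigengenes", function(object)
  standardGeneric("moduleEigengenes"))
setMethod("moduleEigengenes", "ModulePartition", function(object)
  object@eigengenes)

#' @describeIn ModulePartition-class genes x modules kME matrix.
#' @export
setGeneric("moduleKME", function(object) standardGeneric("moduleKME"))
setMethod("moduleKME", "ModulePartition", function(object) object@kME)

#' @describeIn ReceptorFeatures-class receptors x pathways score matrix.
#' @param object a \code{ReceptorFeatures}.
#' @export
setGeneric("featureValues", function(object)
  standardGeneric("featureValues"))
setMethod("featureValues", "ReceptorFeatures", function(object)
  object@values)

#' @describeIn ReceptorFeatures-class receptor -> module provenance map.
#' @export
setGeneric("receptorModule", function(object)
  standardGeneric("receptorModule"))
setMethod("receptorModule", "ReceptorFeatures", function(object)
  object@moduleOf)

#' @describeIn LabelSet-class named list of the four label sets.
#' @param object a \code{LabelSet}.
#' @export
setGeneric("labelSets", function(object) standardGeneric("labelSets"))
setMethod("labelSets", "LabelSet", function(object)
  list(positives = object@positives,
       negativesInferred = object@negativesInferred,
       negativesCytokine = object@negativesCytokine,
       unlabeled = object@unlabeled))

#' @describeIn PURates-class rates as a data.frame (receptor, oobCount,
#'   positiveRate).
#' @param object a \code{PURates}.
#' @export
setGeneric("puRates", function(object) standardGeneric("puRates"))
setMethod("puRates", "PURates", function(object)
  data.frame(receptor = object@receptor, oobCount = object@oobCount,
             positiveRate = object@positiveRate,
             row.names = NULL, stringsAsFactors = FALSE))

#' @describeIn ConfusionCounts-class counts as a named integer vector.
#' @param object a \code{ConfusionCounts}.
#' @export
setGeneric("confusionVector", function(object)
  standardGeneric("confusionVector"))
setMethod("confusionVector", "ConfusionCounts", function(object)
  c(tp = object@tp, tn = object@tn, fp = object@fp, fn = object@fn))
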