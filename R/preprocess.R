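## expression accessor shared by all stages: first assay of a
## SummarizedExperiment, or a plain genes x samples matrix
.exprs <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, 1L)
  else as.matrix(x)
}

.setExprs <- function(x, values) {
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, 1L) <- values
    x
  } else values
}

.rowSds <- function(m) {
  n <- ncol(m)
  mu <- rowMeans(m)
  sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
}

#' Filter lowly-expressed and zero-variance genes
#'
#' Retains genes whose raw-scale value (the log is inverted with the stated
#' base and pseudocount) is at least \code{minValue} in at least
#' \code{minFraction} of samples, the "0.1 RPKM in 80\% of samples" style
#' rule, then drops genes with zero variance across samples. Gene order is
#' preserved.
#'
#' @param se \code{SummarizedExperiment} (or matrix) of log-scale values.
#' @param minValue threshold on the raw (pre-log) scale.
#' @param minFraction required fraction of samples at or above
#'   \code{minValue}; in (0, 1].
#' @param logBase,pseudocount the transform assumed for the stored values,
#'   \code{log_logBase(raw + pseudocount)}.
#' @return list with the filtered \code{se} and a \code{report} of removal
#'   counts.
#' @export
filterGenes <- function(se, minValue = 0.1, minFraction = 0.8,
                        logBase = 2, pseudocount = 1) {
  stopifnot(minFraction > 0, minFraction <= 1)
  x <- .exprs(se)
  raw <- logBase^x - pseudocount
  keepExpr <- rowMeans(raw >= minValue) >= minFraction
  keepVar <- .rowSds(x) > 0
  keep <- keepExpr & keepVar
  if (!any(keep))
    stop(sprintf("no genes pass the filter (minValue = %g, minFraction = %g)",
                 minValue, minFraction))
  list(se = se[keep, , drop = FALSE],
       report = list(
         genes_removed_low_expression = sum(!keepExpr),
         genes_removed_zero_variance = sum(keepExpr & !keepVar)))
}

#' Remove outlier samples by standardized connectivity
#'
#' Scores each sample by its mean correlation with all other samples (or,
#' with \code{metric = "euclidean"}, by minus its mean distance),
#' standardizes the scores, and removes samples whose z-score falls below
#' \code{sdCutoff}. If the scores have zero variance no sample is an
#' outlier.
#'
#' @param se expression container with >= 3 samples.
#' @param sdCutoff z-score threshold, default -3.
#' @param metric connectivity metric.
#' @return list with the filtered \code{se} and a \code{report} naming the
#'   removed samples.
#' @export
removeOutlierSamples <- function(se, sdCutoff = -3,
                                 metric = c("correlation", "euclidean")) {
  metric <- match.arg(metric)
  x <- .exprs(se)
  n <- ncol(x)
  if (n < 3) stop("outlier detection requires at least 3 samples")
  score <- if (metric == "correlation") {
    cc <- suppressWarnings(cor(x))
    cc[is.na(cc)] <- 0
    (colSums(cc) - 1) / (n - 1)
  } else {
    d <- as.matrix(dist(t(x)))
    -colSums(d) / (n - 1)
  }
  s <- sd(score)
  z <- if (is.na(s) || s == 0) rep(0, n) else (score - mean(score)) / s
  keep <- z >= sdCutoff
  list(se = se[, keep, drop = FALSE],
       report = list(samples_removed_outlier = sum(!keep),
                     outlier_samples = colnames(x)[!keep]))
}

#' Quantile-normalize samples
#'
#' Forces every sample onto the common reference distribution (the
#' across-sample mean of sorted value vectors); ties receive the mean of the
#' reference values at their rank positions. Backed by
#' \code{limma::normalizeQuantiles}.
#'
#' @param se expression container with finite values.
#' @return the container with normalized values.
#' @export
quantileNormalize <- function(se) {
  x <- .exprs(se)
  if (!all(is.finite(x))) stop("expression values must be finite")
  if (ncol(x) < 2) return(se)
  .setExprs(se, limma::normalizeQuantiles(x, ties = TRUE))
}

#' Discretize sample covariates for batch adjustment
#'
#' Adds \code{ischemic_bin} (300-minute intervals labeled 1--5, capped at 5)
#' and \code{age_bin} (decades, e.g. "30-39") to the sample covariates.
#'
#' @param x a \code{SummarizedExperiment} or a covariate data.frame with
#'   columns \code{ischemic_time_min} and/or \code{age}.
#' @return the same container with the binned columns added.
#' @export
discretizeCovariates <- function(x) {
  cd <- if (methods::is(x, "SummarizedExperiment"))
    SummarizedExperiment::colData(x) else x
  if (!is.null(cd$ischemic_time_min)) {
    t <- cd$ischemic_time_min
    if (any(t < 0, na.rm = TRUE)) stop("negative ischemic times")
    cd$ischemic_bin <- factor(pmin(5, floor(t / 300) + 1), levels = 1:5)
  }
  if (!is.null(cd$age)) {
    lo <- 10 * floor(cd$age / 10)
    cd$age_bin <- factor(sprintf("%d-%d", lo, lo + 9))
  }
  if (methods::is(x, "SummarizedExperiment")) {
    SummarizedExperiment::colData(x) <- cd
    x
  } else cd
}

#' Subset samples by death classification
#'
#' Retains the stated death-class group (the ventilator group by default,
#' chosen for its short ischemic times and preserved sample quality).
#'
#' @param se container whose covariates include \code{death_class}.
#' @param deathClass class to retain.
#' @return the subset container.
#' @export
subsetDeathClass <- function(se, deathClass = "ventilator") {
  dc <- SummarizedExperiment::colData(se)$death_class
  if (is.null(dc)) stop("no death_class covariate present")
  se[, dc == deathClass, drop = FALSE]
}

#' Iteratively adjust expression for known categorical factors
#'
#' For each factor in order, applies a per-gene location-scale correction:
#' within each factor level, values are centred to the gene's grand mean and
#' rescaled so the within-level standard deviation equals the pooled
#' within-level standard deviation. Levels with a single sample are removed
#' before adjusting; genes with zero variance within any level of the
#' current factor are dropped; factors left with fewer than two levels are
#' skipped with a warning. Each factor is adjusted in turn, so later factors
#' see the data already corrected for earlier ones. Each gene's grand mean
#' is preserved exactly.
#'
#' @param se expression container; \code{factors} must name categorical
#'   columns of its sample covariates (discretize first, see
#'   \code{\link{discretizeCovariates}}).
#' @param factors ordered character vector of covariate names.
#' @return list with the adjusted \code{se} and a \code{report} of removal
#'   counts.
#' @export
adjustBatches <- function(se, factors = c("batch", "ischemic_bin", "sex",
                                          "age_bin")) {
  report <- list(batches_removed_singleton = 0L,
                 samples_removed_singleton = 0L,
                 genes_removed_zero_variance_in_level = 0L)
  for (f in factors) {
    fac <- SummarizedExperiment::colData(se)[[f]]
    if (is.null(fac)) stop(sprintf("covariate '%s' not found", f))
    fac <- droplevels(factor(fac))
    singleton <- names(which(table(fac) < 2))
    if (length(singleton)) {
      keep <- !(fac %in% singleton)
      report$batches_removed_singleton <-
        report$batches_removed_singleton + length(singleton)
      report$samples_removed_singleton <-
        report$samples_removed_singleton + sum(!keep)
      se <- se[, keep, drop = FALSE]
      fac <- droplevels(fac[keep])
    }
    if (nlevels(fac) < 2) {
      warning(sprintf("factor '%s' has a single level; skipped", f))
      next
    }
    x <- .exprs(se)
    levIdx <- split(seq_len(ncol(x)), fac)
    sds <- vapply(levIdx, function(idx) .rowSds(x[, idx, drop = FALSE]),
                  numeric(nrow(x)))
    degenerate <- apply(sds == 0, 1, any)
    if (any(degenerate)) {
      report$genes_removed_zero_variance_in_level <-
        report$genes_removed_zero_variance_in_level + sum(degenerate)
      se <- se[!degenerate, , drop = FALSE]
      x <- x[!degenerate, , drop = FALSE]
      sds <- sds[!degenerate, , drop = FALSE]
    }
    grand <- rowMeans(x)
    dfs <- vapply(levIdx, length, 0L) - 1L
    pooled <- sqrt(as.vector(sds^2 %*% dfs) / sum(dfs))
    for (l in seq_along(levIdx)) {
      idx <- levIdx[[l]]
      m <- rowMeans(x[, idx, drop = FALSE])
      x[, idx] <- grand + (x[, idx, drop = FALSE] - m) * (pooled / sds[, l])
    }
    se <- .setExprs(se, x)
  }
  list(se = se, report = report)
}

#' Run the full preprocessing stage
#'
#' Death-class subsetting, expression filtering, outlier-sample removal,
#' quantile normalization, covariate discretization and iterative
#' location-scale batch adjustment, in that order.
#'
#' @param se raw \code{SummarizedExperiment} of log2-scale values with the
#'   sample covariates of \code{\link{simulateReceptorData}}.
#' @param minValue,minFraction gene-filter thresholds
#'   (\code{\link{filterGenes}}).
#' @param sdCutoff outlier threshold (\code{\link{removeOutlierSamples}}).
#' @param deathClass death class to retain, or \code{NULL} to keep all.
#' @param factors adjustment order (\code{\link{adjustBatches}}); factors
#'   absent from the covariates are ignored.
#' @return list with the processed \code{se} and the merged \code{report}.
#' @export
preprocessExpression <- function(se, minValue = 0.1, minFraction = 0.8,
                                 sdCutoff = -3, deathClass = "ventilator",
                                 factors = c("batch", "ischemic_bin", "sex",
                                             "age_bin")) {
  if (!is.null(deathClass) &&
      !is.null(SummarizedExperiment::colData(se)$death_class))
    se <- subsetDeathClass(se, deathClass)
  fg <- filterGenes(se, minValue, minFraction)
  os <- removeOutlierSamples(fg$se, sdCutoff)
  se <- quantileNormalize(os$se)
  se <- discretizeCovariates(se)
  factors <- intersect(factors,
                       colnames(SummarizedExperiment::colData(se)))
  ab <- adjustBatches(se, factors)
  list(se = ab$se, report = c(fg$report, os$report, ab$report))
}
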