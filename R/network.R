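#' Biweight midcorrelation matrix
#'
#' Robust gene-gene correlation: for each gene, values are weighted by
#' closeness to the median via the biweight function
#' \eqn{w_i = (1 - u_i^2)^2 \, 1[|u_i| < 1]} with
#' \eqn{u_i = (x_i - \mathrm{med}(x)) / (9 \cdot \mathrm{MAD}(x))} (MAD
#' unscaled), and the correlation of two genes is the normalized inner
#' product of their weighted deviations. Genes whose MAD is zero fall back
#' to the Pearson deviations for that gene (standard convention); a gene
#' that is exactly constant has no defined correlation and is rejected.
#'
#' @param x genes x samples numeric matrix (or a
#'   \code{SummarizedExperiment}) with >= 4 samples.
#' @return genes x genes symmetric correlation matrix with unit diagonal.
#' @export
bicorMatrix <- function(x) {
  x <- .exprs(x)
  if (ncol(x) < 4) stop("bicor requires at least 4 samples")
  d <- t(apply(x, 1, function(r) {
    med <- median(r)
    madv <- mad(r, constant = 1)
    if (madv == 0) {
      dev <- r - mean(r)
      if (all(dev == 0)) stop("constant gene: correlation undefined")
      return(dev)
    }
    u <- (r - med) / (9 * madv)
    w <- (1 - u^2)^2 * (abs(u) < 1)
    (r - med) * w
  }))
  d <- d / sqrt(rowSums(d^2))
  cc <- tcrossprod(d)
  cc[cc > 1] <- 1
  cc[cc < -1] <- -1
  diag(cc) <- 1
  dimnames(cc) <- list(rownames(x), rownames(x))
  cc
}

#' Soft-threshold adjacency
#'
#' Transforms a correlation matrix into network connection strengths. The
#' signed form (default) is \eqn{a_{ij} = (0.5 (1 + cor_{ij}))^\beta}, so
#' anticorrelated genes get adjacency near 0; the unsigned alternative is
#' \eqn{|cor_{ij}|^\beta}.
#'
#' @param cor symmetric correlation matrix in [-1, 1].
#' @param beta soft-threshold power (>= 1), default 12.
#' @param signed use the signed transform (default TRUE).
#' @return adjacency matrix in [0, 1] with attribute \code{beta}.
#' @export
softAdjacency <- function(cor, beta = 12, signed = TRUE) {
  stopifnot(beta >= 1)
  a <- if (signed) (0.5 * (1 + cor))^beta else abs(cor)^beta
  attr(a, "beta") <- beta
  attr(a, "signed") <- signed
  a
}

#' Topological overlap similarity
#'
#' Combines direct adjacency with shared-neighbour structure:
#' \deqn{TOM_{ij} = \frac{l_{ij} + a_{ij}}{\min(k_i, k_j) + 1 - a_{ij}}}
#' with \eqn{l_{ij} = \sum_{u \ne i,j} a_{iu} a_{uj}} and connectivity
#' \eqn{k_i = \sum_{u \ne i} a_{iu}}; the diagonal is 1 by convention. The
#' dissimilarity used for clustering is \code{1 - TOM}.
#'
#' @param adj symmetric adjacency matrix in [0, 1].
#' @return TOM similarity matrix in [0, 1].
#' @export
tomSimilarity <- function(adj) {
  a <- unclass(adj)
  attributes(a)[c("beta", "signed")] <- NULL
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  denom <- outer(k, k, pmin) + 1 - a
  tom <- (l + a) / denom
  tom[denom == 0] <- 0
  diag(tom) <- 1
  tom[tom > 1] <- 1
  tom[tom < 0] <- 0
  (tom + t(tom)) / 2
}

#' Module eigengene
#'
#' First principal component of a module's gene-standardized expression
#' submatrix, as per-sample scores normalized to unit length and oriented so
#' its correlation with the module's mean standardized expression is
#' non-negative. A single-gene module returns that gene's standardized
#' profile (unit-normalized).
#'
#' @param expr genes x samples matrix (or \code{SummarizedExperiment})
#'   restricted to, or indexed by, the module members.
#' @param members optional gene ids or indices selecting the module.
#' @return named per-sample numeric vector of unit length.
#' @export
moduleEigengene <- function(expr, members = NULL) {
  x <- .exprs(expr)
  if (!is.null(members)) x <- x[members, , drop = FALSE]
  z <- t(scale(t(x)))
  if (nrow(z) == 1L) {
    v <- as.vector(z) / sqrt(sum(z^2))
    names(v) <- colnames(x)
    return(v)
  }
  sv <- svd(z, nu = 0, nv = 1)
  v <- sv$v[, 1]
  if (sum(v * colMeans(z)) < 0) v <- -v
  names(v) <- colnames(x)
  v
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of the TOM dissimilarity, a
#' static cut at \code{cutHeight}, removal of clusters below
#' \code{minModuleSize} (their genes get label 0, "unassigned"), iterative
#' merging of modules whose eigengene dissimilarity \code{1 - cor} is below
#' \code{mergeHeight}, and renumbering by decreasing size so module 1 is the
#' largest.
#'
#' @param tom TOM similarity matrix over the same genes as \code{expr}.
#' @param expr genes x samples expression used for eigengenes and kME.
#' @param minModuleSize smallest retained module, default 30.
#' @param cutHeight static dissimilarity cut height, default 0.995.
#' @param mergeHeight eigengene-dissimilarity merge threshold, default 0.25
#'   (0 disables merging).
#' @return a \code{\link{ModulePartition-class}} object.
#' @export
detectModules <- function(tom, expr, minModuleSize = 30, cutHeight = 0.995,
                          mergeHeight = 0.25) {
  x <- .exprs(expr)
  stopifnot(nrow(tom) == nrow(x))
  genes <- rownames(x)
  tree <- hclust(as.dist(1 - tom), method = "average")
  raw <- cutree(tree, h = cutHeight)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= minModuleSize])
  lab <- integer(length(raw))
  for (i in seq_along(keep)) lab[raw == keep[i]] <- i
  names(lab) <- genes
  if (!any(lab > 0L)) {
    warning("no cluster reaches minModuleSize; all genes unassigned")
    return(methods::new("ModulePartition", membership = lab,
                        eigengenes = matrix(0, ncol(x), 0,
                                            dimnames = list(colnames(x),
                                                            NULL)),
                        kME = matrix(0, nrow(x), 0,
                                     dimnames = list(genes, NULL))))
  }
  mes <- function(lab) {
    labs <- sort(unique(lab[lab > 0L]))
    m <- vapply(labs, function(l) moduleEigengene(x, lab == l),
                numeric(ncol(x)))
    colnames(m) <- labs
    m
  }
  me <- mes(lab)
  ## merge near-identical modules by eigengene correlation
  if (mergeHeight > 0) repeat {
    if (ncol(me) < 2) break
    d <- 1 - cor(me)
    diag(d) <- Inf
    ij <- arrayInd(which.min(d), dim(d))
    if (d[ij] >= mergeHeight) break
    from <- as.integer(colnames(me)[max(ij)])
    into <- as.integer(colnames(me)[min(ij)])
    lab[lab == from] <- into
    me <- mes(lab)
  }
  ## renumber by decreasing size (stable on ties)
  labs <- sort(unique(lab[lab > 0L]))
  ord <- labs[order(-tabulate(lab)[labs], labs)]
  lab <- ifelse(lab > 0L, match(lab, ord), 0L)
  names(lab) <- genes
  me <- mes(lab)
  colnames(me) <- paste0("ME", colnames(me))
  rownames(me) <- colnames(x)
  kme <- cor(t(x), me)
  methods::new("ModulePartition", membership = lab, eigengenes = me,
               kME = kme)
}

#' Eigengene-based connectivity (kME)
#'
#' Correlation of every gene's expression profile with every module
#' eigengene.
#'
#' @param expr genes x samples expression.
#' @param partition a \code{\link{ModulePartition-class}}.
#' @return genes x modules correlation matrix.
#' @export
kmeMatrix <- function(expr, partition) {
  cor(t(.exprs(expr)), moduleEigengenes(partition))
}

#' Scale-free topology fit diagnostic
#'
#' R-squared of the log-log regression of connectivity-bin frequency on mean
#' bin connectivity, for judging a soft-threshold power. Reported as a
#' diagnostic only; the power itself is fixed by the caller.
#'
#' @param adj adjacency matrix.
#' @param nBins number of connectivity bins.
#' @return R-squared in [0, 1] (NA if degenerate).
#' @export
scaleFreeFit <- function(adj, nBins = 10) {
  a <- unclass(adj)
  diag(a) <- 0
  k <- rowSums(a)
  k <- k[k > 0]
  if (length(unique(k)) < 3) return(NA_real_)
  bins <- cut(k, breaks = nBins)
  dk <- tapply(k, bins, mean)
  pk <- tapply(k, bins, length) / length(k)
  ok <- !is.na(dk) & pk > 0
  if (sum(ok) < 3) return(NA_real_)
  summary(stats::lm(log10(pk[ok]) ~ log10(dk[ok])))$r.squared
}
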