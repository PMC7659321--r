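#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability \eqn{P[X \ge k]} of observing at least the actual
#' overlap between a module and a pathway when drawing the module's genes
#' from the universe without replacement (one-sided Fisher exact test). Both
#' sets are restricted to the universe first.
#'
#' @param moduleGenes,pathwayGenes character vectors of gene ids.
#' @param universe character vector of background gene ids (non-empty).
#' @return the raw p-value.
#' @export
hypergeomEnrich <- function(moduleGenes, pathwayGenes, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  m <- intersect(moduleGenes, universe)
  p <- intersect(pathwayGenes, universe)
  k <- length(intersect(m, p))
  phyper(k - 1, length(p), length(universe) - length(p), length(m),
         lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' (\code{stats::p.adjust(..., method = "BH")}), returned in the original
#' order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bhAdjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  p.adjust(p, method = "BH")
}

#' Pathway enrichment of every module
#'
#' Scores each detected module against each pathway by the one-sided
#' hypergeometric test and adjusts p-values by Benjamini-Hochberg within
#' each module (across the pathways tested for that module). The universe
#' defaults to all genes assigned to any module; pathways with no universe
#' genes are dropped with a warning.
#'
#' @param partition a \code{\link{ModulePartition-class}}.
#' @param pathways named list of pathway gene-id vectors.
#' @param universe background gene ids; default all module-assigned genes.
#'   Set to \code{names(moduleMembership(partition))} for "all expressed
#'   genes".
#' @return data.frame with columns \code{module}, \code{pathway},
#'   \code{overlap}, \code{p_raw}, \code{p_adj}; attribute
#'   \code{"universe_size"} records the background used.
#' @export
enrichModules <- function(partition, pathways, universe = NULL) {
  mem <- moduleMembership(partition)
  if (is.null(universe)) universe <- names(mem)[mem > 0L]
  universe <- unique(universe)
  restricted <- lapply(pathways, function(g) intersect(unique(g), universe))
  empty <- lengths(restricted) == 0L
  if (any(empty)) {
    warning(sprintf("%d pathway(s) have no genes in the universe; dropped",
                    sum(empty)))
    restricted <- restricted[!empty]
  }
  labs <- sort(unique(mem[mem > 0L]))
  res <- do.call(rbind, lapply(labs, function(l) {
    mg <- intersect(names(mem)[mem == l], universe)
    praw <- vapply(restricted, function(pg)
      hypergeomEnrich(mg, pg, universe), numeric(1))
    data.frame(module = l, pathway = names(restricted),
               overlap = vapply(restricted, function(pg)
                 length(intersect(mg, pg)), 0L),
               p_raw = praw, p_adj = bhAdjust(praw),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(res, "universe_size") <- length(universe)
  res
}

#' Build the receptor feature matrix from module enrichment
#'
#' Gives every receptor the pathway-enrichment score vector of the module it
#' belongs to: \code{-log10(p_adj)} where the module-pathway pair is
#' significant at \code{alpha}, 0 otherwise. Receptors assigned to no module
#' (label 0) or absent from the partition are excluded and reported, the
#' analogue of receptors "not included in any module".
#'
#' @param partition a \code{\link{ModulePartition-class}}.
#' @param enrichment result of \code{\link{enrichModules}}.
#' @param receptors character vector of receptor gene ids.
#' @param alpha adjusted-p significance threshold, default 0.05.
#' @return a \code{\link{ReceptorFeatures-class}} object.
#' @export
buildFeatureMatrix <- function(partition, enrichment, receptors,
                               alpha = 0.05) {
  mem <- moduleMembership(partition)
  pwIds <- unique(enrichment$pathway)
  labs <- sort(unique(enrichment$module))
  scores <- matrix(0, length(labs), length(pwIds),
                   dimnames = list(labs, pwIds))
  sig <- enrichment$p_adj < alpha
  scores[cbind(match(enrichment$module[sig], labs),
               match(enrichment$pathway[sig], pwIds))] <-
    -log10(enrichment$p_adj[sig])
  known <- receptors[receptors %in% names(mem)]
  assigned <- known[mem[known] > 0L]
  excluded <- setdiff(receptors, assigned)
  if (length(excluded))
    message(sprintf("%d receptor(s) excluded (unassigned or absent)",
                    length(excluded)))
  if (!length(assigned)) stop("no receptor belongs to any module")
  vals <- scores[match(mem[assigned], labs), , drop = FALSE]
  rownames(vals) <- assigned
  methods::new("ReceptorFeatures", values = vals,
               moduleOf = setNames(mem[assigned], assigned),
               excluded = excluded)
}
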