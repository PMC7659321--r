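#' Read a genes x samples expression TSV
#'
#' First column gene ids, header row of sample ids, numeric cells. Ragged
#' rows, duplicate ids and non-numeric cells are fatal with the offending
#' line or id named. When a metadata TSV is supplied its rows are matched
#' to the samples and attached as covariates.
#'
#' @param path expression TSV path.
#' @param metaPath optional sample-metadata TSV (first column sample id).
#' @return a \code{SummarizedExperiment} with assay \code{"exprs"}.
#' @export
readExpressionTSV <- function(path, metaPath = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) != 1L)
    stop(sprintf("ragged TSV: line %d has %d fields (expected %d)",
                 which(nf != nf[1])[1], nf[nf != nf[1]][1], nf[1]))
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene id '%s'", ids[duplicated(ids)][1]))
  if (anyDuplicated(colnames(df)[-1]))
    stop(sprintf("duplicate sample id '%s'",
                 colnames(df)[-1][duplicated(colnames(df)[-1])][1]))
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric cells in column '%s'", names(bad)))
  }
  rownames(m) <- ids
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(metaPath)) {
    meta <- read.delim(metaPath, check.names = FALSE,
                       stringsAsFactors = TRUE)
    rownames(meta) <- as.character(meta[[1]])
    missing <- setdiff(colnames(m), rownames(meta))
    if (length(missing))
      stop(sprintf("metadata covers no sample '%s'", missing[1]))
    cd <- S4Vectors::DataFrame(meta[colnames(m), -1, drop = FALSE])
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = cd)
}

#' Write a genes x samples expression TSV
#'
#' @param se \code{SummarizedExperiment} or matrix.
#' @param path output path.
#' @param idColumn name of the gene-id column, default \code{"gene_id"}.
#' @export
writeExpressionTSV <- function(se, path, idColumn = "gene_id") {
  x <- .exprs(se)
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set name, description, member genes. Duplicate
#' genes within a line are deduplicated; when a universe is supplied, genes
#' outside it are dropped (with a note) and pathways left empty are removed
#' with a warning.
#'
#' @param path GMT path.
#' @param universe optional background gene ids to restrict to.
#' @return named list of gene-id vectors.
#' @export
readGMT <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop(sprintf("GMT line %d has fewer than 3 fields", which(short)[1]))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  if (!is.null(universe)) {
    before <- sum(lengths(sets))
    sets <- lapply(sets, intersect, universe)
    dropped <- before - sum(lengths(sets))
    if (dropped > 0)
      message(sprintf("%d gene(s) outside the expression universe dropped",
                      dropped))
    empty <- lengths(sets) == 0L
    if (any(empty)) {
      warning(sprintf("%d pathway(s) empty after restriction; dropped",
                      sum(empty)))
      sets <- sets[!empty]
    }
  }
  sets
}

#' Write gene sets as GMT
#'
#' @param pathways named list of gene-id vectors.
#' @param path output path.
#' @param descriptions optional descriptions (defaults to the names).
#' @export
writeGMT <- function(pathways, path, descriptions = names(pathways)) {
  writeLines(vapply(seq_along(pathways), function(i)
    paste(c(names(pathways)[i], descriptions[i], pathways[[i]]),
          collapse = "\t"), ""), path)
}

#' Read a one-gene-per-line list
#'
#' @param path file path.
#' @return character vector (blank lines removed).
#' @export
readGeneList <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Validated pipeline configuration
#'
#' Collects input paths and all stage parameters with the method's default
#' values (0.1 expression threshold in 80\% of samples, outlier z-cutoff
#' -3, signed network at power 12, enrichment alpha 0.05, 100 PU bagging
#' rounds, label thresholds 0.7/0.8, 10 CV folds, k grid 1..10). Unknown
#' keys are rejected.
#'
#' @param exprFile,metaFile,gmtFile,receptorFile,seedFile required input
#'   paths (expression TSV, metadata TSV, GMT, receptor list, seed-positive
#'   list).
#' @param cytokineFile optional cytokine-negative list path.
#' @param acceptFile optional accept-list path (default: accept all
#'   candidates).
#' @param outDir output directory.
#' @param ... overrides for the stage parameters listed above.
#' @return a \code{PipelineConfig} list.
#' @export
pipelineConfig <- function(exprFile, metaFile, gmtFile, receptorFile,
                           seedFile, cytokineFile = NULL, acceptFile = NULL,
                           outDir = ".", ...) {
  params <- list(
    minValue = 0.1, minFraction = 0.8, sdCutoff = -3,
    deathClass = "ventilator",
    adjustFactors = c("batch", "ischemic_bin", "sex", "age_bin"),
    beta = 12, signed = TRUE, minModuleSize = 30, cutHeight = 0.995,
    mergeHeight = 0.25, alpha = 0.05,
    t = 100L, k = NULL, cost = 1, minOOB = 10L,
    posThreshold = 0.7, negThreshold = 0.8,
    nFolds = 10, kGrid = 1:10, costGrid = 2^(-5:5),
    metricVariant = "paper", rngSeed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(params))
  if (length(unknown))
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  params[names(dots)] <- dots
  cfg <- c(list(exprFile = exprFile, metaFile = metaFile, gmtFile = gmtFile,
                receptorFile = receptorFile, seedFile = seedFile,
                cytokineFile = cytokineFile, acceptFile = acceptFile,
                outDir = outDir), params)
  required <- c("exprFile", "metaFile", "gmtFile", "receptorFile",
                "seedFile")
  for (f in required)
    if (!file.exists(cfg[[f]]))
      stop(sprintf("input file missing: %s = %s", f, cfg[[f]]))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes preprocessing, network module detection, pathway enrichment,
#' PU-bagging label expansion, classifier evaluation and consensus
#' prediction, writing each stage's outputs plus a provenance JSON (input
#' hashes, parameters, seeds) to the configured directory. Deterministic
#' given identical inputs and configuration.
#'
#' @param config a \code{\link{pipelineConfig}} object.
#' @return invisibly, a list with the in-memory stage results and the
#'   vector of files written.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  outDir <- config$outDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  log <- function(fmt, ...) message(sprintf(paste0("[pipeline] ", fmt), ...))

  se <- readExpressionTSV(config$exprFile, config$metaFile)
  receptors <- readGeneList(config$receptorFile)
  seedPositives <- readGeneList(config$seedFile)
  cytokine <- if (!is.null(config$cytokineFile))
    readGeneList(config$cytokineFile) else character()
  acceptList <- if (!is.null(config$acceptFile))
    readGeneList(config$acceptFile) else "all"

  log("preprocess: %d genes x %d samples in", nrow(se), ncol(se))
  pp <- preprocessExpression(se, config$minValue, config$minFraction,
                             config$sdCutoff, config$deathClass,
                             config$adjustFactors)
  se <- pp$se
  log("preprocess: %d genes x %d samples out (%s)", nrow(se), ncol(se),
      paste(names(pp$report), unlist(lapply(pp$report, function(r)
        paste(r, collapse = ","))), sep = "=", collapse = "; "))

  cc <- bicorMatrix(se)
  adj <- softAdjacency(cc, beta = config$beta, signed = config$signed)
  tom <- tomSimilarity(adj)
  partition <- detectModules(tom, se, config$minModuleSize,
                             config$cutHeight, config$mergeHeight)
  mem <- moduleMembership(partition)
  log("modules: %d detected, %d genes unassigned",
      length(unique(mem[mem > 0])), sum(mem == 0))

  pathways <- readGMT(config$gmtFile, universe = rownames(se))
  enr <- enrichModules(partition, pathways)
  features <- buildFeatureMatrix(partition, enr, receptors, config$alpha)
  log("features: %d receptors x %d pathways (%d excluded)",
      nrow(featureValues(features)), ncol(featureValues(features)),
      length(features@excluded))

  seedAvail <- intersect(seedPositives, rownames(featureValues(features)))
  log("seed positives available after module filtering: %d of %d",
      length(seedAvail), length(seedPositives))
  rates <- puBagging(features, seedAvail, t = config$t, k = config$k,
                     cost = config$cost, minOOB = config$minOOB,
                     rngSeed = config$rngSeed)
  labels <- deriveLabels(rates, config$posThreshold, config$negThreshold,
                         acceptList, seedPositives = seedAvail,
                         cytokineReceptors = cytokine)

  metrics <- list()
  models <- list()
  x <- featureValues(features)
  for (ng in c("inferred", "cytokine")) {
    sets <- labelSets(labels)
    negIds <- if (ng == "inferred") sets$negativesInferred
              else sets$negativesCytokine
    if (!length(intersect(negIds, rownames(x)))) next
    ld <- labeledData(features, labels, ng)
    cost <- tuneSvmCost(ld$x, ld$y, config$costGrid, config$nFolds,
                        config$rngSeed)
    kSel <- selectKnnK(ld$x, ld$y, config$kGrid, config$nFolds,
                       config$rngSeed)
    for (method in c("svm", "knn")) {
      counts <- crossValidate(ld$x, ld$y, method, cost = cost, k = kSel,
                              nFolds = config$nFolds,
                              rngSeed = config$rngSeed)
      key <- paste(method, ng, sep = "_")
      metrics[[key]] <- c(as.list(confusionVector(counts)),
                          computeMetrics(counts, config$metricVariant))
      models[[key]] <- fitClassifier(ld$x, ld$y, method, cost = cost,
                                     k = kSel)
    }
  }

  unl <- intersect(labelSets(labels)$unlabeled, rownames(x))
  cons <- consensusPredict(x[unl, , drop = FALSE], models)
  log("consensus: %d of %d unlabeled receptors predicted metabolic",
      length(cons$consensus), length(unl))

  ## stage outputs
  files <- c(expression = file.path(outDir, "expression_processed.tsv"),
             modules = file.path(outDir, "modules.tsv"),
             eigengenes = file.path(outDir, "eigengenes.tsv"),
             enrichment = file.path(outDir, "enrichment.tsv"),
             features = file.path(outDir, "features.tsv"),
             rates = file.path(outDir, "pu_rates.tsv"),
             labels = file.path(outDir, "labels.tsv"),
             metrics = file.path(outDir, "metrics.json"),
             predictions = file.path(outDir, "predictions.tsv"),
             provenance = file.path(outDir, "provenance.json"))
  writeExpressionTSV(se, files["expression"])
  kme <- moduleKME(partition)
  own <- ifelse(mem > 0, kme[cbind(seq_along(mem), mem)], NA_real_)
  write.table(data.frame(gene_id = names(mem), module = mem,
                         kME_own_module = own),
              files["modules"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(sample_id = rownames(moduleEigengenes(partition)),
                         moduleEigengenes(partition), check.names = FALSE),
              files["eigengenes"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(enr, files["enrichment"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeExpressionTSV(featureValues(features), files["features"],
                     idColumn = "receptor")
  write.table(puRates(rates), files["rates"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  sets <- labelSets(labels)
  labDf <- data.frame(
    receptor = unlist(sets, use.names = FALSE),
    label = rep(c("pos", "neg_inferred", "neg_cytokine", "unlabeled"),
                lengths(sets)))
  write.table(labDf, files["labels"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(metrics, files["metrics"], auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  predDf <- data.frame(receptor = unl, cons$votes, check.names = FALSE,
                       consensus = unl %in% cons$consensus)
  write.table(predDf, files["predictions"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  inputs <- c(config$exprFile, config$metaFile, config$gmtFile,
              config$receptorFile, config$seedFile)
  prov <- list(package = "MetReceptor",
               version = as.character(utils::packageVersion("MetReceptor")),
               parameters = config[setdiff(names(config),
                                           c("outDir"))],
               input_md5 = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(prov, files["provenance"], auto_unbox = TRUE,
                       digits = NA, force = TRUE, null = "null")
  invisible(list(se = se, partition = partition, enrichment = enr,
                 features = features, rates = rates, labels = labels,
                 metrics = metrics, models = models, consensus = cons,
                 report = pp$report, files = files))
}
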