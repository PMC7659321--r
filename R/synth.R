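#' Configuration for the synthetic receptor-expression generator
#'
#' Bundles and validates the parameters of \code{\link{simulateReceptorData}}.
#' Defaults define the package's standard study conditions: 600 genes, three
#' planted modules of 100 genes, 160 samples, 60 receptors of which 40\% are
#' metabolic, module loading 1.5 against unit noise, two experimental
#' batches, and 15 pathways of 10--50 genes drawn at 0.8 purity from their
#' target modules.
#'
#' @param nGenes total number of genes.
#' @param nSamples number of samples.
#' @param moduleSizes integer vector of planted module sizes; genes beyond
#'   \code{sum(moduleSizes)} are uncorrelated background. May be empty (no
#'   planted structure).
#' @param nReceptors number of receptor genes.
#' @param fracMetabolic fraction of receptors planted in the metabolic
#'   module (module 1).
#' @param moduleSignal loading of module genes on their latent factor
#'   (unitless, >= 0); 0 removes all planted co-expression.
#' @param noiseSd residual Gaussian noise standard deviation (log2 units).
#' @param nBatches number of experimental batches.
#' @param batchShiftSd standard deviation of the additive per-gene,
#'   per-batch shifts (log2 units).
#' @param nPathways number of pathway gene sets; the first
#'   \code{3 * length(moduleSizes)} target the planted modules (three per
#'   module), the remainder are background-only.
#' @param pathwaySizeRange integer range pathway sizes are drawn from.
#' @param pathwayPurity fraction of a targeted pathway's genes drawn from
#'   its target module (the rest come from background).
#' @param seedPositiveFrac fraction of metabolic receptors revealed as the
#'   initial positive seed list.
#' @param ventilatorFrac fraction of samples assigned the "ventilator" death
#'   class (the class retained by preprocessing).
#' @param rngSeed integer seed; the generator is fully deterministic given
#'   the configuration.
#'
#' @return a validated \code{SyntheticConfig} list.
#' @export
syntheticConfig <- function(nGenes = 600L, nSamples = 160L,
                            moduleSizes = c(100L, 100L, 100L),
                            nReceptors = 60L, fracMetabolic = 0.4,
                            moduleSignal = 1.5, noiseSd = 1,
                            nBatches = 2L, batchShiftSd = 0.5,
                            nPathways = 15L,
                            pathwaySizeRange = c(10L, 50L),
                            pathwayPurity = 0.8,
                            seedPositiveFrac = 1 / 3,
                            ventilatorFrac = 0.75,
                            rngSeed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nSamples = as.integer(nSamples),
              moduleSizes = as.integer(moduleSizes),
              nReceptors = as.integer(nReceptors),
              fracMetabolic = fracMetabolic, moduleSignal = moduleSignal,
              noiseSd = noiseSd, nBatches = as.integer(nBatches),
              batchShiftSd = batchShiftSd, nPathways = as.integer(nPathways),
              pathwaySizeRange = as.integer(pathwaySizeRange),
              pathwayPurity = pathwayPurity,
              seedPositiveFrac = seedPositiveFrac,
              ventilatorFrac = ventilatorFrac, rngSeed = as.integer(rngSeed))
  counts <- c(cfg$nGenes, cfg$nSamples, cfg$nReceptors, cfg$nBatches,
              cfg$nPathways)
  if (any(counts < 1L)) stop("all counts must be positive")
  if (any(cfg$moduleSizes < 1L)) stop("module sizes must be positive")
  if (sum(cfg$moduleSizes) > cfg$nGenes)
    stop("sum(moduleSizes) exceeds nGenes")
  if (cfg$nReceptors > cfg$nGenes) stop("nReceptors exceeds nGenes")
  fr <- c(cfg$fracMetabolic, cfg$pathwayPurity, cfg$seedPositiveFrac,
          cfg$ventilatorFrac)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (cfg$moduleSignal < 0 || cfg$noiseSd < 0 || cfg$batchShiftSd < 0)
    stop("signal and noise parameters must be non-negative")
  nMet <- round(cfg$nReceptors * cfg$fracMetabolic)
  if (length(cfg$moduleSizes) && nMet > cfg$moduleSizes[1])
    stop("metabolic receptor count exceeds the size of module 1")
  class(cfg) <- "SyntheticConfig"
  cfg
}

#' Simulate expression data with planted co-expression modules
#'
#' Generates a complete synthetic input set for the pipeline under a
#' latent-factor model: each planted module m has one standard-normal factor
#' per sample, and a member gene's expression is
#' \code{mean + loading * factor_m + batchShift + noise}. Background genes
#' have loading 0. Metabolic receptors are placed in module 1 (the
#' designated metabolic module); non-metabolic receptors are spread over the
#' remaining modules and background, with the module-2 receptors doubling as
#' the cytokine-style negative list. Targeted pathways draw
#' \code{pathwayPurity} of their genes from their target module so that
#' module-pathway enrichment reflects the planted structure.
#'
#' @param config a \code{\link{syntheticConfig}} object.
#'
#' @return a list with elements
#' \describe{
#'   \item{se}{\code{SummarizedExperiment} with assay \code{"exprs"}
#'     (genes x samples, log2-scale values) and sample covariates
#'     \code{batch}, \code{ischemic_time_min}, \code{sex}, \code{age},
#'     \code{death_class}.}
#'   \item{pathways}{named list of pathway gene-id vectors.}
#'   \item{receptors}{character vector of receptor gene ids.}
#'   \item{seedPositives}{initial positive seed subset of the metabolic
#'     receptors.}
#'   \item{cytokineReceptors}{non-metabolic receptors in module 2, the
#'     stand-in for an independent cytokine-receptor list.}
#'   \item{truth}{ground truth: \code{moduleOfGene} (0 = background),
#'     \code{metabolicReceptors}, \code{nonmetabolicReceptors},
#'     \code{pathwayTargetModule} (0 = background pathway), and the latent
#'     \code{factors} matrix (modules x samples).}
#' }
#' @export
simulateReceptorData <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$rngSeed)
  nG <- config$nGenes; nS <- config$nSamples
  sizes <- config$moduleSizes
  nMod <- length(sizes)
  geneIds <- sprintf("g%04d", seq_len(nG))
  sampleIds <- sprintf("s%03d", seq_len(nS))

  moduleOf <- integer(nG)
  if (nMod) moduleOf[seq_len(sum(sizes))] <- rep(seq_len(nMod), sizes)
  names(moduleOf) <- geneIds

  factors <- matrix(rnorm(max(nMod, 1L) * nS), nrow = max(nMod, 1L),
                    dimnames = list(NULL, sampleIds))
  if (!nMod) factors <- factors[0L, , drop = FALSE]

  batch <- sample(rep_len(seq_len(config$nBatches), nS))
  shift <- matrix(rnorm(nG * config$nBatches, sd = config$batchShiftSd),
                  nrow = nG)
  means <- runif(nG, 2, 8)

  expr <- matrix(rnorm(nG * nS, sd = config$noiseSd), nrow = nG,
                 dimnames = list(geneIds, sampleIds))
  expr <- expr + means + shift[cbind(rep(seq_len(nG), nS),
                                     rep(batch, each = nG))]
  inMod <- moduleOf > 0L
  if (any(inMod))
    expr[inMod, ] <- expr[inMod, ] +
      config$moduleSignal * factors[moduleOf[inMod], , drop = FALSE]

  covar <- S4Vectors::DataFrame(
    batch = factor(paste0("b", batch)),
    ischemic_time_min = round(runif(nS, 0, 1500), 1),
    sex = factor(sample(c("M", "F"), nS, replace = TRUE)),
    age = sample(21:79, nS, replace = TRUE),
    death_class = factor(sample(
      c("ventilator", "fast_violent", "fast_natural", "slow"), nS,
      replace = TRUE,
      prob = c(config$ventilatorFrac,
               rep((1 - config$ventilatorFrac) / 3, 3)))),
    row.names = sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = expr), colData = covar)

  ## receptors: metabolic in module 1; the rest over other modules and
  ## background (module-2 receptors double as the cytokine-list analogue)
  nMet <- if (nMod) round(config$nReceptors * config$fracMetabolic) else 0L
  modGenes <- lapply(seq_len(nMod), function(m) geneIds[moduleOf == m])
  bgGenes <- geneIds[moduleOf == 0L]
  metabolic <- if (nMet) sort(sample(modGenes[[1]], nMet)) else character()
  nNon <- config$nReceptors - nMet
  nonPools <- c(if (nMod > 1) modGenes[-1] else list(), list(bgGenes))
  alloc <- diff(round(seq(0, nNon, length.out = length(nonPools) + 1)))
  nonmetabolic <- sort(unlist(mapply(function(pool, n) {
    if (n > length(pool)) stop("receptor count exceeds available genes")
    sample(pool, n)
  }, nonPools, alloc, SIMPLIFY = FALSE)))
  receptors <- sort(c(metabolic, nonmetabolic))
  seedPositives <- if (length(metabolic))
    sort(sample(metabolic, max(1L, round(length(metabolic) *
                                           config$seedPositiveFrac))))
  else character()
  cytokine <- if (nMod > 1)
    sort(intersect(nonmetabolic, modGenes[[2]])) else character()

  ## pathways: three per module target that module at the configured purity
  nTarget <- min(3L * nMod, config$nPathways)
  targetOf <- integer(config$nPathways)
  if (nTarget) targetOf[seq_len(nTarget)] <- rep(seq_len(nMod),
                                                 length.out = nTarget)
  pwIds <- sprintf("pw%02d", seq_len(config$nPathways))
  names(targetOf) <- pwIds
  pathways <- lapply(seq_len(config$nPathways), function(i) {
    size <- sample(seq(config$pathwaySizeRange[1],
                       config$pathwaySizeRange[2]), 1)
    tm <- targetOf[i]
    if (tm > 0L) {
      nIn <- min(round(config$pathwayPurity * size), length(modGenes[[tm]]))
      sort(c(sample(modGenes[[tm]], nIn),
             sample(bgGenes, min(size - nIn, length(bgGenes)))))
    } else {
      sort(sample(bgGenes, min(size, length(bgGenes))))
    }
  })
  names(pathways) <- pwIds

  list(se = se, pathways = pathways, receptors = receptors,
       seedPositives = seedPositives, cytokineReceptors = cytokine,
       truth = list(moduleOfGene = moduleOf,
                    metabolicReceptors = metabolic,
                    nonmetabolicReceptors = nonmetabolic,
                    pathwayTargetModule = targetOf,
                    factors = factors))
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the expression TSV, sample-metadata TSV, pathway GMT, receptor and
#' seed-positive lists, and the ground truth as JSON, in the layout the
#' pipeline readers expect.
#'
#' @param data result of \code{\link{simulateReceptorData}}.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths written.
#' @export
writeSyntheticData <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             pathways = file.path(dir, "pathways.gmt"),
             receptors = file.path(dir, "receptors.txt"),
             seed_positives = file.path(dir, "seed_positives.txt"),
             cytokine_receptors = file.path(dir, "cytokine_receptors.txt"),
             truth = file.path(dir, "truth.json"))
  writeExpressionTSV(data$se, paths["expression"])
  meta <- as.data.frame(SummarizedExperiment::colData(data$se))
  meta <- cbind(sample_id = rownames(meta), meta)
  write.table(meta, paths["metadata"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeGMT(data$pathways, paths["pathways"])
  writeLines(data$receptors, paths["receptors"])
  writeLines(data$seedPositives, paths["seed_positives"])
  writeLines(data$cytokineReceptors, paths["cytokine_receptors"])
  truth <- data$truth
  truth$factors <- NULL
  jsonlite::write_json(truth, paths["truth"], auto_unbox = FALSE,
                       digits = NA)
  invisible(paths)
}
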