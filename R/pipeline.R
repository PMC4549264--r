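# End-to-end pipeline driver: simulate (or ingest) -> occupancy -> calling
# -> sequence features -> metaprofiles/clustering -> methylation geometry
# -> architecture scan, with a reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Chains every stage on synthetic data (or user-supplied fragment/genome
#' files) and writes all outputs plus a manifest (parameter echo, seed,
#' md5 checksum per output) to \code{outDir}.  Re-running with the same
#' configuration reproduces the checksums.
#'
#' @param outDir output directory (created if needed).
#' @param config a \linkS4class{SimConfig}; its seed drives every
#'   stochastic stage.
#' @param scanCfg a \linkS4class{ScanConfig}.
#' @param stages character subset of
#'   \code{c("simulate", "nos", "call", "seqfreq", "profiles",
#'   "methylation", "scan")}; later stages require earlier ones.
#' @param genomePath,fragmentsPath,chromSizesPath optional paths replacing
#'   the simulated genome/fragments; checked before any stage runs.
#' @param flank metaprofile half-window (bp).
#' @param kClusters clusters for the TSS architecture k-means.
#' @return The manifest (named list), invisibly; also written as
#'   \code{manifest.yaml}.
#' @export
runPipeline <- function(outDir, config = simConfig(),
                        scanCfg = scanConfig(),
                        stages = c("simulate", "nos", "call", "seqfreq",
                                   "profiles", "methylation", "scan"),
                        genomePath = NULL, fragmentsPath = NULL,
                        chromSizesPath = NULL,
                        flank = 1000L, kClusters = 10L) {
  stages <- match.arg(stages, several.ok = TRUE)
  for (p in c(genomePath, fragmentsPath, chromSizesPath)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file does not exist: ", p)
    }
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  emit <- function(writer, obj, name, ...) {
    path <- file.path(outDir, name)
    writer(obj, path, ...)
    outputs <<- c(outputs, path)
    path
  }
  stageRun <- function(name, code) {
    tryCatch(code, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  sim <- NULL; genome <- NULL; fragments <- NULL; chromSizes <- NULL
  if ("simulate" %in% stages) {
    sim <- stageRun("simulate", simulateDataset(config))
    genome <- sim$genome
    fragments <- sim$fragments
    chromSizes <- setNames(Biostrings::width(genome), names(genome))
    emit(writeGenomeFasta, genome, "genome.fa")
    emit(writeBed, fragments, "fragments.bed")
    emit(writeGenesBed12, sim$genes, "genes.bed12")
    emit(writeBedGraph, sim$rnaPlus, "rna_plus.bedGraph")
    emit(writeBedGraph, sim$rnaMinus, "rna_minus.bedGraph")
    emit(writeMethylationTsv, sim$methylation, "methylation.tsv")
    emit(writeBed, sim$truth$enhancerSites, "truth_enhancers.bed")
    emit(writeChromSizes, chromSizes, "chrom.sizes")
  }
  if (!is.null(chromSizesPath)) chromSizes <- readChromSizes(chromSizesPath)
  if (!is.null(genomePath)) {
    genome <- readGenomeFasta(genomePath)
    chromSizes <- setNames(Biostrings::width(genome), names(genome))
  }
  if (!is.null(fragmentsPath)) {
    fragments <- readBed(fragmentsPath, chromSizes)
  }

  nos <- NULL; nosNorm <- NULL; nucs <- NULL
  if ("nos" %in% stages) {
    if (is.null(fragments)) stop("'nos' stage requires fragments")
    nos <- stageRun("nos", {
      computeNOS(deduplicateFragments(fragments), chromSizes)
    })
    nosNorm <- normalizeTracks(nos)
    emit(writeBedGraph, nosNorm, "nos.bedGraph")
    emit(writeWiggle, nosNorm, "nos.wig")
  }
  if ("call" %in% stages) {
    if (is.null(nos)) stop("'call' stage requires the 'nos' stage")
    nucs <- stageRun("call", callNucleosomes(nosNorm))
    emit(writeNucleosomesBed, nucs, "nucleosomes.bed")
  }
  if ("seqfreq" %in% stages) {
    if (is.null(genome) || is.null(nucs)) {
      stop("'seqfreq' stage requires a genome and called nucleosomes")
    }
    stageRun("seqfreq", {
      prof <- dyadRelativeFrequency(genome, nucs, k = 2)
      path <- file.path(outDir, "dinucleotide_profile.tsv")
      write.table(t(prof), path, sep = "\t", quote = FALSE,
                  col.names = NA)
      outputs <<- c(outputs, path)
      pg <- fftPeriodogram(prof["AA", ])
      path <- file.path(outDir, "aa_periodogram.tsv")
      write.table(data.frame(period = pg@periods, power = pg@power),
                  path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path)
    })
  }
  if ("profiles" %in% stages && !is.null(sim)) {
    stageRun("profiles", {
      rna <- buildRnaSignal(sim$rnaPlus, sim$rnaMinus)
      expr <- totalExpression(sim$genes, rna)
      q <- quartileSplit(expr)
      mat <- profileMatrix(nosNorm, sim$genes, flank = flank)
      km <- kmeansProfiles(mat, k = kClusters,
                           seed = config@seed)
      path <- file.path(outDir, "tss_clusters.tsv")
      write.table(data.frame(gene = names(km$assignments),
                             cluster = km$assignments,
                             quartile = as.character(q)[match(
                               names(km$assignments), names(expr))]),
                  path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path)
      path <- file.path(outDir, "tss_mean_profile.tsv")
      prof <- aggregateProfile(nosNorm, sim$genes, flank = flank)
      write.table(data.frame(offset = names(prof), nos = prof), path,
                  sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path)
    })
  }
  if ("methylation" %in% stages && !is.null(sim)) {
    stageRun("methylation", {
      hist <- distanceToNearestDyad(sim$methylation, nucs,
                                    context = "mCG")
      path <- file.path(outDir, "mcg_dyad_distance.tsv")
      write.table(hist, path, sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path)
      cts <- assignSitesToNucleosomes(sim$methylation, nucs)
      strat <- occupancyByCount(nucs, cts, "mCG")
      path <- file.path(outDir, "mcg_occupancy_strata.tsv")
      write.table(cbind(strat$groups, kwP = strat$kwP), path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
      outputs <<- c(outputs, path)
    })
  }
  hits <- NULL
  if ("scan" %in% stages) {
    if (is.null(nucs)) stop("'scan' stage requires called nucleosomes")
    hits <- stageRun("scan", findPatterns(nucs, nosNorm, scanCfg))
    sc <- hits$score
    hits$score <- if (length(sc)) round(1000 * sc / max(sc)) else numeric(0)
    hits$name <- sprintf("hit%d", seq_along(hits))
    emit(writeBed, hits, "pattern_hits.bed", ncols = 6L)
    if (!is.null(genome) && length(hits)) {
      emit(function(obj, path) writeGenomeFasta(obj, path),
           extractHitSequences(genome, hits), "candidates.fa")
    }
  }

  manifest <- list(
    package = "nucarch",
    version = as.character(utils::packageVersion("nucarch")),
    seed = config@seed,
    stages = stages,
    parameters = list(
      genomeLength = config@genomeLength, nChroms = config@nChroms,
      nFragments = config@nFragments, nGenes = config@nGenes,
      nrl = config@nrl, coreWidth = config@coreWidth,
      posScoreMin = scanCfg@posScoreMin,
      gapRange = scanCfg@gapRange),
    outputs = lapply(setNames(nm = basename(outputs)), function(b) {
      unname(tools::md5sum(file.path(outDir, b)))
    }))
  yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
  invisible(manifest)
}
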