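#' @import methods
#' @importFrom BiocGenerics sort
#' @importFrom stats rnorm runif rbinom quantile median cor fft kruskal.test
#'   wilcox.test p.adjust qnorm pnorm acf kmeans setNames aggregate
#' @importFrom utils head tail read.table write.table
NULL

CONTEXTS <- c("mCG", "mCHG", "mCHH", "hmC")

#' Per-base genome signal track
#'
#' A \code{GenomeTrack} holds one numeric value per base for each chromosome,
#' e.g. a nucleosome occupancy score (NOS) map or an RNA signal.  The
#' \code{depthFactor} slot records the cumulative scaling applied by
#' \code{\link{normalizeTracks}} (1 for a raw track).
#'
#' @slot values named list of numeric vectors, one per chromosome; values are
#'   finite and non-negative.
#' @slot depthFactor single numeric, cumulative normalization factor.
#' @slot metadata list of optional bookkeeping (e.g. rejected fragment count).
#' @aliases GenomeTrack
#' @export
setClass("GenomeTrack",
  representation(values = "list", depthFactor = "numeric", metadata = "list"),
  prototype(values = list(), depthFactor = 1, metadata = list())
)

setValidity("GenomeTrack", function(object) {
  v <- object@values
  if (length(v) && is.null(names(v))) return("'values' must be a named list")
  if (!all(vapply(v, is.numeric, logical(1)))) {
    return("'values' must contain numeric vectors")
  }
  bad <- vapply(v, function(x) anyNA(x) || any(!is.finite(x)) || any(x < 0),
                logical(1))
  if (any(bad)) return("track values must be finite and >= 0")
  if (length(object@depthFactor) != 1 || object@depthFactor <= 0) {
    return("'depthFactor' must be a single positive number")
  }
  TRUE
})

#' Construct a GenomeTrack
#'
#' @param values named list of per-chromosome numeric vectors.
#' @param depthFactor cumulative normalization factor (1 = raw).
#' @param metadata optional list of bookkeeping values.
#' @return A \linkS4class{GenomeTrack}.
#' @examples
#' tr <- GenomeTrack(list(chr1 = rep(1, 100)))
#' trackMean(tr)
#' @export
GenomeTrack <- function(values, depthFactor = 1, metadata = list()) {
  new("GenomeTrack", values = values, depthFactor = depthFactor,
      metadata = metadata)
}

#' @describeIn GenomeTrack-class chromosome names.
#' @param x,object a \code{GenomeTrack}.
#' @export
setMethod("names", "GenomeTrack", function(x) names(x@values))

#' Track accessors
#'
#' \code{trackValues} returns the per-base values of one chromosome (or the
#' full named list), \code{trackChromLengths} the chromosome lengths, and
#' \code{trackMean} the mean value over all chromosomes.
#'
#' @param x a \linkS4class{GenomeTrack}.
#' @param chrom chromosome name; \code{NULL} returns the full list.
#' @return Numeric vector(s) of per-base values, lengths, or a single mean.
#' @export
trackValues <- function(x, chrom = NULL) {
  stopifnot(is(x, "GenomeTrack"))
  if (is.null(chrom)) return(x@values)
  if (!chrom %in% names(x@values)) {
    stop("chromosome '", chrom, "' not in track")
  }
  x@values[[chrom]]
}

#' @rdname trackValues
#' @export
trackChromLengths <- function(x) {
  vapply(x@values, length, numeric(1))
}

#' @rdname trackValues
#' @export
trackMean <- function(x) {
  tot <- sum(vapply(x@values, sum, numeric(1)))
  n <- sum(trackChromLengths(x))
  if (n == 0) stop("empty track")
  tot / n
}

setMethod("show", "GenomeTrack", function(object) {
  lens <- trackChromLengths(object)
  cat("GenomeTrack with", length(lens), "chromosome(s),",
      format(sum(lens), big.mark = ","), "bp\n")
  if (length(lens)) {
    cat("  mean value:", signif(trackMean(object), 4),
        "| depthFactor:", signif(object@depthFactor, 4), "\n")
  }
})

#' Periodicity spectrum of a positional signal
#'
#' Result of \code{\link{fftPeriodogram}} or \code{\link{phasingPeriodogram}}:
#' in-band periods (bp), their spectral power, and the dominant period when a
#' significant, interior spectral peak exists (\code{NA} otherwise).
#'
#' @slot periods numeric, periods (bp) of the in-band frequency grid.
#' @slot power numeric, squared-magnitude spectrum at those periods.
#' @slot band numeric(2), period band searched (bp).
#' @slot dominantPeriod single numeric or NA: interpolated dominant period.
#' @slot peakRatio single numeric: peak power / median in-band power.
#' @aliases Periodogram
#' @export
setClass("Periodogram",
  representation(periods = "numeric", power = "numeric", band = "numeric",
                 dominantPeriod = "numeric", peakRatio = "numeric"),
  prototype(dominantPeriod = NA_real_, peakRatio = NA_real_)
)

setValidity("Periodogram", function(object) {
  if (length(object@periods) != length(object@power)) {
    return("'periods' and 'power' lengths differ")
  }
  if (any(object@power < 0)) return("'power' must be non-negative")
  if (length(object@band) != 2 || object@band[1] >= object@band[2]) {
    return("'band' must be an increasing pair")
  }
  dp <- object@dominantPeriod
  if (!is.na(dp) && (dp < object@band[1] || dp > object@band[2])) {
    return("'dominantPeriod' lies outside 'band'")
  }
  TRUE
})

#' Extract the dominant period
#'
#' @param x a \linkS4class{Periodogram}.
#' @return Single numeric period in bp, or \code{NA} when no significant
#'   periodicity was detected.
#' @export
dominantPeriod <- function(x) {
  stopifnot(is(x, "Periodogram"))
  x@dominantPeriod
}

setMethod("show", "Periodogram", function(object) {
  cat("Periodogram over band [", object@band[1], ", ", object@band[2],
      "] bp, ", length(object@periods), " frequencies\n", sep = "")
  if (is.na(object@dominantPeriod)) {
    cat("  dominant period: none (peak ratio ",
        signif(object@peakRatio, 3), ")\n", sep = "")
  } else {
    cat("  dominant period:", round(object@dominantPeriod, 2), "bp",
        "(peak ratio", paste0(signif(object@peakRatio, 3), ")"), "\n")
  }
})

#' Synthetic-dataset configuration
#'
#' Parameters of the ground-truth simulator: genome geometry, nucleosome
#' landscape, fragment sampling noise, gene annotation structure, and
#' dyad-coupled methylation placement.  Build with \code{\link{simConfig}},
#' which supplies the documented defaults.
#'
#' @slot genomeLength bp per chromosome.
#' @slot nChroms number of chromosomes.
#' @slot gcBackground background G+C fraction of linker DNA.
#' @slot gcCoreBoost additional G+C fraction inside nucleosome cores.
#' @slot coreWidth nucleosome core width in bp (odd; 147).
#' @slot periodicDinucleotidePeriod period (bp) of AA/TT placement in cores.
#' @slot periodicAmplitude relative amplitude in [0,1] of the sinusoidal
#'   AA/TT placement modulation.
#' @slot periodicBaseRate mean per-offset probability of forcing an AA/TT
#'   dinucleotide start inside a core.
#' @slot nrl nucleosome repeat length (bp).
#' @slot fragLenMean,fragLenSd fragment length distribution (bp).
#' @slot fragLenRange truncation bounds for fragment lengths (bp).
#' @slot jitterSdPositioned,jitterSdFuzzy dyad jitter s.d. (bp) by class.
#' @slot dupRate probability that a fragment is emitted with a PCR duplicate.
#' @slot nFragments number of fragments sampled by
#'   \code{\link{sampleFragments}}.
#' @slot nGenes,nProfileClasses gene count and number of TSS architecture
#'   classes.
#' @slot expressionTiers relative expression rates, including 0 for silent.
#' @slot positionedFraction fraction of array nucleosomes that are
#'   well-positioned (the rest are fuzzy).
#' @slot nEnhancers number of planted enhancer-architecture sites.
#' @slot methDensityByContext named per-bp site rates for
#'   mCG/mCHG/mCHH/hmC.
#' @slot methCoreFraction named per-context probability that a site is
#'   placed inside a core (the rest go to linkers uniformly).
#' @slot methDyadProfile named list of dyad-relative placement densities
#'   over offsets -73..+73 (each non-negative, summing to 1).
#' @slot seed integer master seed; every generator op derives a fixed
#'   substream from it.
#' @aliases SimConfig
#' @export
setClass("SimConfig",
  representation(
    genomeLength = "numeric", nChroms = "integer",
    gcBackground = "numeric", gcCoreBoost = "numeric",
    coreWidth = "integer",
    periodicDinucleotidePeriod = "numeric", periodicAmplitude = "numeric",
    periodicBaseRate = "numeric",
    nrl = "numeric",
    fragLenMean = "numeric", fragLenSd = "numeric", fragLenRange = "numeric",
    jitterSdPositioned = "numeric", jitterSdFuzzy = "numeric",
    dupRate = "numeric", nFragments = "integer",
    nGenes = "integer", nProfileClasses = "integer",
    expressionTiers = "numeric", positionedFraction = "numeric",
    nEnhancers = "integer",
    methDensityByContext = "numeric", methCoreFraction = "numeric",
    methDyadProfile = "list",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  frac <- c(gcBackground = object@gcBackground,
            gcCoreBoost = object@gcCoreBoost,
            periodicAmplitude = object@periodicAmplitude,
            periodicBaseRate = object@periodicBaseRate,
            dupRate = object@dupRate,
            positionedFraction = object@positionedFraction)
  if (any(frac < 0 | frac > 1)) {
    return(paste("fractions must lie in [0,1]:",
                 paste(names(frac)[frac < 0 | frac > 1], collapse = ", ")))
  }
  lens <- c(object@genomeLength, object@nChroms, object@coreWidth,
            object@nrl, object@fragLenMean, object@nFragments,
            object@periodicDinucleotidePeriod)
  if (any(lens <= 0)) return("all lengths and counts must be > 0")
  if (object@coreWidth %% 2L != 1L) {
    return("coreWidth must be odd (a unique central dyad base must exist)")
  }
  if (object@fragLenSd < 0 || object@jitterSdPositioned < 0 ||
      object@jitterSdFuzzy < 0) {
    return("standard deviations must be >= 0")
  }
  if (length(object@fragLenRange) != 2 ||
      object@fragLenRange[1] >= object@fragLenRange[2]) {
    return("fragLenRange must be an increasing pair")
  }
  if (object@nProfileClasses > object@nGenes) {
    return("nProfileClasses must not exceed nGenes")
  }
  if (!length(object@expressionTiers) || any(object@expressionTiers < 0)) {
    return("expressionTiers must be non-negative rates")
  }
  ctx <- names(object@methDensityByContext)
  if (!all(ctx %in% CONTEXTS)) {
    return(paste("unknown methylation context; allowed:",
                 paste(CONTEXTS, collapse = ", ")))
  }
  half <- (object@coreWidth - 1L) %/% 2L
  for (cc in ctx) {
    pr <- object@methDyadProfile[[cc]]
    if (is.null(pr)) {
      return(paste0("context '", cc, "' has no methDyadProfile"))
    }
    if (length(pr) != object@coreWidth || any(pr < 0) ||
        abs(sum(pr) - 1) > 1e-8) {
      return(paste0("methDyadProfile[['", cc, "']] must be a non-negative ",
                    "density of length ", object@coreWidth, " summing to 1"))
    }
    cf <- object@methCoreFraction[cc]
    if (is.na(cf) || cf < 0 || cf > 1) {
      return(paste0("methCoreFraction['", cc, "'] must lie in [0,1]"))
    }
  }
  if (length(object@seed) != 1 || is.na(object@seed)) {
    return("seed must be a single integer")
  }
  TRUE
})

#' Default dyad-relative methylation placement densities
#'
#' mCG mass concentrates at the dyad and at +/- 40 bp (the three strongest
#' DNA--histone contact regions); mCHG has a single broad dyad-centred mode;
#' mCHH is nearly flat inside the core (most of its mass goes to linkers via
#' \code{methCoreFraction}); hmC has broad off-centre modes.
#'
#' @param coreWidth odd core width in bp (default 147).
#' @return Named list of densities over offsets \code{-(w-1)/2 .. +(w-1)/2}.
#' @export
defaultMethProfiles <- function(coreWidth = 147L) {
  half <- (coreWidth - 1L) %/% 2L
  p <- -half:half
  g <- function(mu, sd) exp(-0.5 * ((p - mu) / sd)^2)
  norm1 <- function(x) x / sum(x)
  list(
    mCG  = norm1(0.2 + g(0, 8) + g(-40, 8) + g(40, 8)),
    mCHG = norm1(0.2 + g(0, 25)),
    mCHH = norm1(rep(1, length(p))),
    hmC  = norm1(0.3 + g(-55, 12) + g(55, 12))
  )
}

#' Construct a simulation configuration
#'
#' Defaults describe a desk-scale study: 2 chromosomes of 1 Mb (~10,800
#' nucleosomes at a 185 bp repeat), 200,000 fragments of mean length 151 bp,
#' a 147 bp core with ~10 bp periodic AA/TT placement, 200 genes in 10 TSS
#' architecture classes and 4 expression tiers, 24 planted
#' enhancer-architecture sites, and dyad-coupled methylation in four
#' contexts.
#'
#' @param genomeLength,nChroms genome geometry.
#' @param gcBackground,gcCoreBoost base composition (linker GC fraction and
#'   the additional GC enrichment inside cores).
#' @param coreWidth nucleosome core width (odd bp).
#' @param periodicDinucleotidePeriod,periodicAmplitude,periodicBaseRate
#'   AA/TT placement model inside cores.
#' @param nrl nucleosome repeat length (bp).
#' @param fragLenMean,fragLenSd,fragLenRange fragment length model (bp).
#' @param jitterSdPositioned,jitterSdFuzzy dyad jitter by positioning class.
#' @param dupRate PCR duplicate rate.
#' @param nFragments fragments to sample.
#' @param nGenes,nProfileClasses,expressionTiers gene annotation model.
#' @param positionedFraction fraction of array nucleosomes well-positioned.
#' @param nEnhancers planted enhancer-architecture sites.
#' @param methDensityByContext,methCoreFraction,methDyadProfile methylation
#'   placement model (see \code{\link{defaultMethProfiles}}).
#' @param seed master seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(genomeLength = 5e4, nChroms = 1L, nGenes = 10L,
#'                  nFragments = 5000L)
#' cfg
#' @export
simConfig <- function(genomeLength = 1e6, nChroms = 2L,
                      gcBackground = 0.40, gcCoreBoost = 0.15,
                      coreWidth = 147L,
                      periodicDinucleotidePeriod = 10,
                      periodicAmplitude = 0.6,
                      periodicBaseRate = 0.10,
                      nrl = 185,
                      fragLenMean = 151, fragLenSd = 15,
                      fragLenRange = c(100, 220),
                      jitterSdPositioned = 10, jitterSdFuzzy = 20,
                      dupRate = 0.1,
                      nFragments = 600000L,
                      nGenes = 200L, nProfileClasses = 10L,
                      expressionTiers = c(0, 1, 2, 4),
                      positionedFraction = 0.7,
                      nEnhancers = 24L,
                      methDensityByContext = c(mCG = 0.010, mCHG = 0.002,
                                               mCHH = 0.005, hmC = 0.001),
                      methCoreFraction = c(mCG = 0.85, mCHG = 0.75,
                                           mCHH = 0.20, hmC = 0.50),
                      methDyadProfile = defaultMethProfiles(coreWidth),
                      seed = 42L) {
  new("SimConfig",
      genomeLength = genomeLength, nChroms = as.integer(nChroms),
      gcBackground = gcBackground, gcCoreBoost = gcCoreBoost,
      coreWidth = as.integer(coreWidth),
      periodicDinucleotidePeriod = periodicDinucleotidePeriod,
      periodicAmplitude = periodicAmplitude,
      periodicBaseRate = periodicBaseRate,
      nrl = nrl,
      fragLenMean = fragLenMean, fragLenSd = fragLenSd,
      fragLenRange = fragLenRange,
      jitterSdPositioned = jitterSdPositioned,
      jitterSdFuzzy = jitterSdFuzzy,
      dupRate = dupRate, nFragments = as.integer(nFragments),
      nGenes = as.integer(nGenes),
      nProfileClasses = as.integer(nProfileClasses),
      expressionTiers = expressionTiers,
      positionedFraction = positionedFraction,
      nEnhancers = as.integer(nEnhancers),
      methDensityByContext = methDensityByContext,
      methCoreFraction = methCoreFraction,
      methDyadProfile = methDyadProfile,
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChroms, "chromosome(s) x",
      format(object@genomeLength, big.mark = ","), "bp |",
      object@nGenes, "genes |", object@nFragments, "fragments\n")
  cat("  core", object@coreWidth, "bp | NRL", object@nrl,
      "bp | AA/TT period", object@periodicDinucleotidePeriod,
      "bp (amplitude", paste0(object@periodicAmplitude, ")"), "| seed",
      object@seed, "\n")
})

#' Enhancer-architecture scan configuration
#'
#' Thresholds of \code{\link{findPatterns}}: the pattern is a depleted
#' region between two well-positioned nucleosomes, themselves flanked by
#' further well-positioned nucleosomes.
#'
#' @slot posScoreMin minimum positioning score of the two bounding
#'   nucleosomes and of the flank-support nucleosomes.
#' @slot gapRange allowed inter-dyad gap (bp) across the depleted region.
#' @slot troughFracMax the NOS minimum in the gap must be at most this
#'   fraction of the smaller bounding summit.
#' @slot minFlankSupport additional well-positioned nucleosomes required on
#'   each outer side.
#' @slot flankSearchBp distance (bp) searched for flank support.
#' @aliases ScanConfig
#' @export
setClass("ScanConfig",
  representation(posScoreMin = "numeric", gapRange = "numeric",
                 troughFracMax = "numeric", minFlankSupport = "integer",
                 flankSearchBp = "numeric")
)

setValidity("ScanConfig", function(object) {
  if (length(object@gapRange) != 2 || object@gapRange[1] >= object@gapRange[2]) {
    return("gapRange must be an increasing pair")
  }
  if (object@gapRange[1] <= 147) {
    return("gapRange minimum must exceed the 147 bp core width")
  }
  if (object@posScoreMin < 1) return("posScoreMin must be >= 1")
  if (object@troughFracMax <= 0 || object@troughFracMax > 1) {
    return("troughFracMax must lie in (0, 1]")
  }
  if (object@minFlankSupport < 0) return("minFlankSupport must be >= 0")
  if (object@flankSearchBp <= 0) return("flankSearchBp must be > 0")
  TRUE
})

#' Construct a scan configuration
#'
#' @param posScoreMin,gapRange,troughFracMax,minFlankSupport,flankSearchBp
#'   see \linkS4class{ScanConfig}.
#' @return A validated \linkS4class{ScanConfig}.
#' @export
scanConfig <- function(posScoreMin = 1.5, gapRange = c(250, 600),
                       troughFracMax = 0.5, minFlankSupport = 1L,
                       flankSearchBp = 450) {
  new("ScanConfig", posScoreMin = posScoreMin, gapRange = gapRange,
      troughFracMax = troughFracMax,
      minFlankSupport = as.integer(minFlankSupport),
      flankSearchBp = flankSearchBp)
}

setMethod("show", "ScanConfig", function(object) {
  cat("ScanConfig: positioning score >=", object@posScoreMin,
      "| gap", object@gapRange[1], "-", object@gapRange[2], "bp",
      "| trough <=", object@troughFracMax, "x summit",
      "|", object@minFlankSupport, "support/side within",
      object@flankSearchBp, "bp\n")
})
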