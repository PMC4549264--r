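# Ground-truth simulator: genome, nucleosome landscape, fragments,
# annotations, RNA signal and methylation with known parameters.
#
# All randomness is derived from SimConfig@seed through fixed per-stage
# substreams (landscape +0, sequence +1, fragments +2, annotations +3,
# methylation +4), so each generator op is independently reproducible and
# the global RNG state of the caller is left untouched.

.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

.half <- function(config) (config@coreWidth - 1L) %/% 2L

.chromNamesOf <- function(config) paste0("chr", seq_len(config@nChroms))

.splitCount <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

# TSS architecture classes: (side of the major well-positioned promoter
# nucleosome, its |offset| from the TSS).  Classes 1..ceiling(K/2) put the
# major peak downstream (+1), the rest upstream (-1), offsets stepping by
# 50 bp from 60 bp.
.classTable <- function(K) {
  nDown <- ceiling(K / 2)
  data.frame(
    class = seq_len(K),
    side = c(rep("down", nDown), rep("up", K - nDown)),
    offset = 160 + 40 * (c(seq_len(nDown), seq_len(K - nDown)) - 1)
  )
}

.tierRank <- function(tier, tiers) match(tier, sort(unique(tiers))) - 1L

# Deterministic landscape shared by every generator op: gene models with
# architecture class and expression tier, the true nucleosome set (dyad,
# positioning class, occupancy weight, role), and planted enhancer sites.
.simLandscape <- function(config) .withSeed(config@seed, {
  L <- config@genomeLength
  chromNames <- .chromNamesOf(config)
  gPer <- .splitCount(config@nGenes, config@nChroms)
  ePer <- .splitCount(config@nEnhancers, config@nChroms)
  ctab <- .classTable(config@nProfileClasses)
  tiers <- config@expressionTiers
  nrl <- config@nrl
  geneLen <- 3000L
  minDist <- 150L

  genesL <- list(); nucsL <- list(); enhL <- list()
  usedTss <- integer(0)

  for (ci in seq_len(config@nChroms)) {
    g <- gPer[ci]
    if (g == 0) next
    terr <- floor(L / g)
    if (terr < 2 * (geneLen + 1600)) {
      stop("genomeLength too small for the requested gene count: each gene ",
           "needs ~", 2 * (geneLen + 1600), " bp of territory, got ", terr)
    }
    anchors <- (seq_len(g) - 1) * terr + floor(terr / 2)
    tss <- as.integer(anchors + sample(-1000:1000, g, replace = TRUE))
    # unique TSS across the whole gene set
    while (anyDuplicated(c(usedTss, tss))) {
      dup <- duplicated(c(usedTss, tss))[length(usedTss) + seq_len(g)]
      tss[dup] <- tss[dup] + 1L
    }
    usedTss <- c(usedTss, tss)
    strand <- sample(c("+", "-"), g, replace = TRUE)
    cls <- sample(rep_len(seq_len(config@nProfileClasses), g))
    tier <- sample(tiers, g, replace = TRUE)
    rk <- .tierRank(tier, tiers)
    s <- ifelse(strand == "+", 1L, -1L)

    dy <- wt <- numeric(0); pcls <- role <- character(0); gid <- integer(0)
    protect <- NULL  # intervals kept nucleosome-free (NDRs, enhancer troughs)

    for (i in seq_len(g)) {
      side <- ctab$side[cls[i]]; off <- ctab$offset[cls[i]]
      # expression coupling: stronger +1 (major), emptier NDR (filler,
      # minor) as the tier rises
      wMajor <- 1.5 + 0.5 * rk[i]
      wMinor <- 0.5 * 0.6^rk[i]
      wNdr <- 0.35 * 0.45^rk[i]
      dMaj <- if (side == "down") off else -off
      dMin <- if (side == "down") -160 else 160
      dDown <- max(dMaj, dMin); dUp <- min(dMaj, dMin)
      offs <- c(dMaj, dMin, 0,
                dDown + nrl * seq_len(floor((geneLen + 400 - dDown) / nrl)),
                dUp - nrl * (1:2))
      rl <- c("major", "minor", "ndrFiller",
              rep("array", length(offs) - 5L), rep("array", 2L))
      w0 <- c(wMajor, wMinor, wNdr, rep(NA, length(offs) - 3L))
      pc <- c("positioned", "fuzzy", "fuzzy", rep(NA, length(offs) - 3L))
      isArr <- is.na(w0)
      arrPos <- runif(sum(isArr)) < config@positionedFraction
      pc[isArr] <- ifelse(arrPos, "positioned", "fuzzy")
      w0[isArr] <- ifelse(arrPos, 1, 0.7)
      d <- tss[i] + s[i] * as.integer(round(offs))
      dy <- c(dy, d); wt <- c(wt, w0); pcls <- c(pcls, pc)
      role <- c(role, rl); gid <- c(gid, rep(i, length(d)))
      lo <- min(tss[i] + s[i] * dMaj, tss[i] + s[i] * dMin)
      hi <- max(tss[i] + s[i] * dMaj, tss[i] + s[i] * dMin)
      protect <- rbind(protect, c(lo + 1, hi - 1))
    }

    # planted enhancer architecture at gene-territory boundaries: a ~400 bp
    # inter-dyad NDR bounded by strongly positioned nucleosomes with one
    # additional positioned support nucleosome on each side
    eb <- integer(0)
    if (ePer[ci] > 0 && g > 1) {
      bounds <- terr * seq_len(g - 1)
      eb <- bounds[unique(round(seq(1, g - 1, length.out = ePer[ci])))]
      for (b in eb) {
        dy <- c(dy, b - 385, b - 200, b + 200, b + 385)
        wt <- c(wt, 2, 3, 3, 2)
        pcls <- c(pcls, rep("positioned", 4))
        role <- c(role, "enhSupport", "enhFlank", "enhFlank", "enhSupport")
        gid <- c(gid, rep(NA_integer_, 4))
        protect <- rbind(protect, c(b - 330, b + 330))
      }
    }

    # fill remaining gaps with NRL-spaced arrays (evenly respaced so no
    # spurious >250 bp inter-dyad gaps arise at junctions)
    o <- order(dy)
    dSort <- dy[o]
    gapL <- c(100, dSort); gapR <- c(dSort, L - 100)
    fills <- numeric(0)
    for (j in seq_along(gapL)) {
      G <- gapR[j] - gapL[j]
      if (G < 300) next
      # choose the fill count whose even spacing stays near the NRL while
      # avoiding sub-170 bp gaps (which make dyad attribution ambiguous)
      cand <- seq_len(max(1L, ceiling(G / 150)))
      sp <- G / (cand + 1)
      pen <- abs(sp - nrl) + 1e4 * (sp < 170 | sp > 250)
      n <- cand[which.min(pen)]
      if (G / (n + 1) < 150) next
      fills <- c(fills, gapL[j] + (G / (n + 1)) * seq_len(n))
    }
    fills <- as.integer(round(fills))
    if (!is.null(protect) && length(fills)) {
      bad <- rep(FALSE, length(fills))
      for (j in seq_len(nrow(protect))) {
        bad <- bad | (fills >= protect[j, 1] & fills <= protect[j, 2])
      }
      fills <- fills[!bad]
    }
    if (length(fills)) {
      fPos <- runif(length(fills)) < config@positionedFraction
      dy <- c(dy, fills)
      wt <- c(wt, ifelse(fPos, 1, 0.7))
      pcls <- c(pcls, ifelse(fPos, "positioned", "fuzzy"))
      role <- c(role, rep("intergenic", length(fills)))
      gid <- c(gid, rep(NA_integer_, length(fills)))
    }

    # continuous occupancy variation: array and intergenic nucleosomes get
    # a lognormal weight multiplier (planted promoter/enhancer roles keep
    # their exact weights so parameter-recovery margins stay interpretable)
    isBulk <- role %in% c("array", "intergenic")
    wt[isBulk] <- wt[isBulk] * exp(rnorm(sum(isBulk), 0, 0.4))

    # enforce the >= 150 bp inter-dyad invariant, keeping heavier
    # nucleosomes (deterministic: weight desc, then position)
    keepIn <- dy >= 100 & dy <= L - 100
    dy <- dy[keepIn]; wt <- wt[keepIn]; pcls <- pcls[keepIn]
    role <- role[keepIn]; gid <- gid[keepIn]
    o <- order(-wt, dy)
    keep <- logical(length(dy))
    kept <- integer(0)
    for (j in o) {
      if (!length(kept) || all(abs(kept - dy[j]) >= minDist)) {
        keep[j] <- TRUE
        kept <- c(kept, dy[j])
      }
    }
    o2 <- order(dy[keep])
    idx <- which(keep)[o2]

    chrom <- chromNames[ci]
    gStart <- ifelse(strand == "+", tss, tss - geneLen + 1L)
    gEnd <- ifelse(strand == "+", tss + geneLen - 1L, tss)
    genesL[[chrom]] <- data.frame(
      chrom = chrom, start = gStart, end = gEnd, strand = strand,
      tss = tss, class = cls, tier = tier,
      name = sprintf("%s_g%03d", chrom, seq_len(g)),
      stringsAsFactors = FALSE)
    nucsL[[chrom]] <- data.frame(
      chrom = chrom, dyad = as.integer(dy[idx]), class = pcls[idx],
      occupancyWeight = wt[idx], role = role[idx],
      geneIndex = gid[idx], stringsAsFactors = FALSE)
    if (length(eb)) {
      enhL[[chrom]] <- data.frame(chrom = chrom, center = as.integer(eb),
                                  stringsAsFactors = FALSE)
    }
  }

  chromLens <- setNames(rep(config@genomeLength, config@nChroms), chromNames)
  list(chromLens = chromLens,
       genes = do.call(rbind, genesL),
       nucleosomes = do.call(rbind, nucsL),
       enhancers = if (length(enhL)) do.call(rbind, enhL) else
         data.frame(chrom = character(0), center = integer(0)))
})

.truthGRanges <- function(land) {
  nu <- land$nucleosomes
  gr <- GenomicRanges::GRanges(
    nu$chrom, IRanges::IRanges(start = nu$dyad, width = 1L),
    class = nu$class, occupancyWeight = nu$occupancyWeight,
    role = nu$role, geneIndex = nu$geneIndex,
    seqlengths = land$chromLens)
  names(gr) <- NULL
  gr
}

.genesGRanges <- function(land) {
  ge <- land$genes
  GenomicRanges::GRanges(
    ge$chrom, IRanges::IRanges(ge$start, ge$end), strand = ge$strand,
    tss = ge$tss, class = ge$class, tier = ge$tier, name = ge$name,
    seqlengths = land$chromLens)
}

#' Generate a synthetic genome with embedded nucleosome sequence preferences
#'
#' Lays nucleosomes at the configured repeat length with nucleosome-depleted
#' regions at gene TSSs and planted enhancer sites, then synthesizes
#' sequence: linkers use the background base composition; each 147 bp core
#' mixes a GC-enriched background with AA/TT dinucleotide placement whose
#' per-offset probability is modulated sinusoidally at the configured period
#' and amplitude, phase-locked to the dyad.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A list with \code{genome} (named \code{DNAStringSet}) and
#'   \code{nucleosomes}: a \code{GRanges} of true dyads (width 1) with
#'   metadata columns \code{class} (positioned/fuzzy), \code{occupancyWeight}
#'   and \code{role}.
#' @examples
#' cfg <- simConfig(genomeLength = 6e4, nChroms = 1L, nGenes = 5L,
#'                  nFragments = 1000L, nEnhancers = 2L)
#' gg <- generateGenome(cfg)
#' gg$genome
#' length(gg$nucleosomes)
#' @export
generateGenome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  land <- .simLandscape(config)
  truth <- .truthGRanges(land)
  half <- .half(config)
  genome <- .withSeed(config@seed + 1L, {
    seqs <- lapply(names(land$chromLens), function(chrom) {
      L <- land$chromLens[[chrom]]
      dyads <- land$nucleosomes$dyad[land$nucleosomes$chrom == chrom]
      .synthesizeChrom(L, dyads, config, half)
    })
    names(seqs) <- names(land$chromLens)
    Biostrings::DNAStringSet(unlist(seqs))
  })
  list(genome = genome, nucleosomes = truth)
}

.baseProbs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

.synthesizeChrom <- function(L, dyads, config, half) {
  bg <- .baseProbs(config@gcBackground)
  bases <- sample(names(bg), L, replace = TRUE, prob = bg)
  if (length(dyads)) {
    gcCore <- min(1, config@gcBackground + config@gcCoreBoost)
    coreP <- .baseProbs(gcCore)
    offs <- -half:half
    coreIdx <- as.vector(outer(dyads, offs, `+`))
    coreIdx <- coreIdx[coreIdx >= 1 & coreIdx <= L]
    coreIdx <- unique(coreIdx)
    bases[coreIdx] <- sample(names(coreP), length(coreIdx),
                             replace = TRUE, prob = coreP)
    # sinusoidal AA/TT placement, phase-locked to the dyad
    pOff <- -half:(half - 1L)  # dinucleotide start offsets inside the core
    rate <- config@periodicBaseRate *
      (1 + config@periodicAmplitude *
         cos(2 * pi * pOff / config@periodicDinucleotidePeriod))
    rate <- pmin(pmax(rate, 0), 1)
    hit <- matrix(runif(length(dyads) * length(pOff)) <
                    rep(rate, each = length(dyads)),
                  nrow = length(dyads))
    pos <- as.vector(outer(dyads, pOff, `+`))[as.vector(hit)]
    pos <- sort(pos[pos >= 1 & pos <= L - 1])
    if (length(pos)) {
      keep <- logical(length(pos))
      last <- -10L
      for (j in seq_along(pos)) {      # drop overlapping placements
        if (pos[j] - last >= 2L) { keep[j] <- TRUE; last <- pos[j] }
      }
      pos <- pos[keep]
      motif <- sample(c("A", "T"), length(pos), replace = TRUE)
      bases[pos] <- motif
      bases[pos + 1L] <- motif
    }
  }
  paste(bases, collapse = "")
}

#' Sample mononucleosomal fragments around true dyads
#'
#' Each fragment is drawn around a true dyad chosen proportionally to its
#' occupancy weight; the fragment midpoint is the dyad plus Gaussian jitter
#' with a class-dependent standard deviation, and the length is Normal
#' (truncated to \code{fragLenRange}).  PCR duplicates are injected by
#' emitting each record with an extra copy with probability \code{dupRate}.
#' Records are returned sorted.
#'
#' @param truth \code{GRanges} of true dyads as produced by
#'   \code{\link{generateGenome}} (metadata \code{class},
#'   \code{occupancyWeight}).
#' @param config a \linkS4class{SimConfig}.
#' @param n number of pre-duplication fragments (default
#'   \code{config@nFragments}).
#' @return Sorted \code{GRanges} of fragment intervals.
#' @export
sampleFragments <- function(truth, config, n = config@nFragments) {
  stopifnot(is(config, "SimConfig"), is(truth, "GRanges"))
  if (!length(truth)) stop("'truth' must contain at least one nucleosome")
  .withSeed(config@seed + 2L, {
    w <- truth$occupancyWeight
    if (is.null(w)) w <- rep(1, length(truth))
    idx <- sample.int(length(truth), n, replace = TRUE, prob = w)
    sdJ <- ifelse(truth$class[idx] == "positioned",
                  config@jitterSdPositioned, config@jitterSdFuzzy)
    mid <- GenomicRanges::start(truth)[idx] + as.integer(round(rnorm(n, 0, sdJ)))
    if (config@fragLenSd == 0) {
      len <- rep(as.integer(round(config@fragLenMean)), n)
    } else {
      lo <- config@fragLenRange[1]; hi <- config@fragLenRange[2]
      u <- runif(n, pnorm(lo - 0.5, config@fragLenMean, config@fragLenSd),
                 pnorm(hi + 0.5, config@fragLenMean, config@fragLenSd))
      len <- pmin(hi, pmax(lo, as.integer(round(
        qnorm(u, config@fragLenMean, config@fragLenSd)))))
    }
    start <- mid - (len - 1L) %/% 2L
    end <- start + len - 1L
    chrom <- as.character(GenomicRanges::seqnames(truth))[idx]
    lens <- GenomeInfoDb::seqlengths(truth)
    ok <- start >= 1L & end <= lens[chrom]
    chrom <- chrom[ok]; start <- start[ok]; end <- end[ok]
    dup <- rbinom(length(start), 1L, config@dupRate)
    rep_idx <- rep(seq_along(start), 1L + dup)
    gr <- GenomicRanges::GRanges(
      chrom[rep_idx], IRanges::IRanges(start[rep_idx], end[rep_idx]),
      seqlengths = lens)
    sort(gr)
  })
}

#' Generate gene models, RNA signal, feature annotations and truth bundle
#'
#' Genes have unique TSSs, random strands, one of
#' \code{nProfileClasses} TSS architecture classes (distinct well-positioned
#' +1/-1 placements) and an expression tier.  Stranded RNA signal tracks are
#' emitted consistent with the tiers (the 0 tier is silent); promoter
#' histone-mark intervals (H3K4me3 for the top tier, H3K27me3 for silent,
#' both marks for intermediate = bivalent), chromatin-state intervals and
#' TFBS intervals are consistent with tiers and planted enhancers.
#'
#' @param config a \linkS4class{SimConfig}.
#' @return A list with \code{genes} (GRanges with \code{tss}, \code{class},
#'   \code{tier}), \code{rnaPlus}/\code{rnaMinus} (\linkS4class{GenomeTrack}),
#'   \code{tfbs}, \code{marks}, \code{states} (GRanges), and \code{truth}:
#'   the truth bundle (gene classes/tiers, enhancer sites, methylation
#'   placement parameters).
#' @export
generateAnnotations <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  land <- .simLandscape(config)
  genes <- .genesGRanges(land)
  chromLens <- land$chromLens
  .withSeed(config@seed + 3L, {
    plus <- lapply(chromLens, function(L) numeric(L))
    minus <- lapply(chromLens, function(L) numeric(L))
    exprNoise <- exp(rnorm(length(genes), 0, 0.25))
    for (i in seq_along(genes)) {
      if (genes$tier[i] == 0) next
      chrom <- as.character(GenomicRanges::seqnames(genes))[i]
      span <- GenomicRanges::start(genes)[i]:GenomicRanges::end(genes)[i]
      v <- genes$tier[i] * exprNoise[i]
      if (as.character(GenomicRanges::strand(genes))[i] == "+") {
        plus[[chrom]][span] <- plus[[chrom]][span] + v
      } else {
        minus[[chrom]][span] <- minus[[chrom]][span] + v
      }
    }
    tiers <- sort(unique(config@expressionTiers))
    topTier <- max(tiers)
    promoter <- function(i, flank = 500L) {
      tss <- genes$tss[i]
      IRanges::IRanges(max(1L, tss - flank), tss + flank)
    }
    marksL <- list()
    statesL <- list()
    tfbsL <- list()
    for (i in seq_along(genes)) {
      chrom <- as.character(GenomicRanges::seqnames(genes))[i]
      pr <- promoter(i)
      tier <- genes$tier[i]
      mk <- if (tier == topTier) "H3K4me3"
            else if (tier == 0) "H3K27me3" else "bivalent"
      marks <- if (mk == "bivalent") c("H3K4me3", "H3K27me3") else mk
      marksL[[length(marksL) + 1L]] <- data.frame(
        chrom = chrom, start = IRanges::start(pr), end = IRanges::end(pr),
        mark = marks, gene = genes$name[i])
      st <- if (tier == topTier) "TssA"
            else if (tier == 0) "ReprPC" else "TssBiv"
      statesL[[length(statesL) + 1L]] <- data.frame(
        chrom = chrom, start = IRanges::start(pr), end = IRanges::end(pr),
        state = st)
      if (tier > 0) {
        statesL[[length(statesL) + 1L]] <- data.frame(
          chrom = chrom, start = GenomicRanges::start(genes)[i],
          end = GenomicRanges::end(genes)[i], state = "Tx")
      }
      if (tier == topTier) {  # promoter TFBS at active genes
        tfbsL[[length(tfbsL) + 1L]] <- data.frame(
          chrom = chrom, start = genes$tss[i] - 100L,
          end = genes$tss[i] + 99L, kind = "promoter")
      }
    }
    enh <- land$enhancers
    if (nrow(enh)) {
      tfbsL[[length(tfbsL) + 1L]] <- data.frame(
        chrom = enh$chrom, start = enh$center - 100L,
        end = enh$center + 99L, kind = "enhancer")
      statesL[[length(statesL) + 1L]] <- data.frame(
        chrom = enh$chrom, start = enh$center - 100L,
        end = enh$center + 99L, state = "Enh")
    }
    dfgr <- function(df, extra) {
      gr <- GenomicRanges::GRanges(df$chrom,
                                   IRanges::IRanges(df$start, df$end),
                                   seqlengths = chromLens)
      for (nm in extra) S4Vectors::mcols(gr)[[nm]] <- df[[nm]]
      sort(gr)
    }
    marksDf <- do.call(rbind, marksL)
    statesDf <- do.call(rbind, statesL)
    tfbsDf <- do.call(rbind, tfbsL)
    enhGr <- GenomicRanges::GRanges(
      enh$chrom, IRanges::IRanges(enh$center - 100L, enh$center + 99L),
      seqlengths = chromLens)
    truthBundle <- list(
      geneClasses = setNames(genes$class, genes$name),
      geneTiers = setNames(genes$tier, genes$name),
      enhancerSites = enhGr,
      methylationTruth = list(profiles = config@methDyadProfile,
                              coreFraction = config@methCoreFraction,
                              densities = config@methDensityByContext))
    list(genes = genes,
         rnaPlus = GenomeTrack(plus),
         rnaMinus = GenomeTrack(minus),
         tfbs = dfgr(tfbsDf, "kind"),
         marks = dfgr(marksDf, c("mark", "gene")),
         states = dfgr(statesDf, "state"),
         truth = truthBundle)
  })
}

#' Generate methylation sites coupled to nucleosome dyads
#'
#' Per context, sites are placed inside nucleosome cores with probability
#' \code{methCoreFraction[context]} (choosing the nucleosome proportionally
#' to its occupancy weight and the dyad-relative offset from
#' \code{methDyadProfile[[context]]}) and uniformly in linkers otherwise.
#' mCG placement in high-occupancy nucleosomes (weight >= 2) is tilted
#' towards the dyad.  When \code{genome} is supplied, placements are
#' rejection-sampled onto C/G bases (strandless cytosines).
#'
#' @param truth \code{GRanges} of true dyads (see
#'   \code{\link{generateGenome}}).
#' @param config a \linkS4class{SimConfig}.
#' @param genome optional named \code{DNAStringSet}.
#' @return Sorted \code{GRanges} (width 1) with a \code{context} metadata
#'   column.
#' @export
generateMethylation <- function(truth, config, genome = NULL) {
  stopifnot(is(config, "SimConfig"), is(truth, "GRanges"))
  half <- .half(config)
  ctxs <- names(config@methDensityByContext)
  for (cc in ctxs) {
    if (is.null(config@methDyadProfile[[cc]])) {
      stop("context '", cc, "' has no dyad placement profile")
    }
  }
  chromLens <- GenomeInfoDb::seqlengths(truth)
  if (anyNA(chromLens)) stop("'truth' must carry seqlengths")
  totalLen <- sum(chromLens)
  dyadsByChrom <- split(GenomicRanges::start(truth),
                        as.character(GenomicRanges::seqnames(truth)))
  dyadsByChrom <- lapply(dyadsByChrom, sort)
  isCG <- function(chrom, pos) {
    if (is.null(genome)) return(rep(TRUE, length(pos)))
    b <- substring(as.character(genome[[chrom]]), pos, pos)
    b == "C" | b == "G"
  }
  .withSeed(config@seed + 4L, {
    out <- list()
    w <- truth$occupancyWeight
    if (is.null(w)) w <- rep(1, length(truth))
    trChrom <- as.character(GenomicRanges::seqnames(truth))
    trDyad <- GenomicRanges::start(truth)
    for (cc in ctxs) {
      nSites <- round(config@methDensityByContext[[cc]] * totalLen)
      if (nSites == 0) next
      nCore <- rbinom(1L, nSites, config@methCoreFraction[[cc]])
      posC <- character(0); posP <- integer(0)
      if (nCore > 0) {
        need <- nCore
        for (try in 1:8) {
          if (need <= 0) break
          idx <- sample.int(length(truth), need, replace = TRUE, prob = w)
          off <- sample(-half:half, need, replace = TRUE,
                        prob = config@methDyadProfile[[cc]])
          if (cc == "mCG") {
            hi <- w[idx] >= 2 & runif(need) < 0.5
            if (any(hi)) {
              off[hi] <- pmax(-half, pmin(half,
                as.integer(round(rnorm(sum(hi), 0, 8)))))
            }
          }
          p <- trDyad[idx] + off
          ch <- trChrom[idx]
          ok <- p >= 1 & p <= chromLens[ch]
          if (!is.null(genome)) {
            ok2 <- rep(FALSE, length(p))
            for (chrom in unique(ch[ok])) {
              ii <- which(ok & ch == chrom)
              ok2[ii] <- isCG(chrom, p[ii])
            }
            ok <- ok & ok2
          }
          posC <- c(posC, ch[ok]); posP <- c(posP, p[ok])
          need <- nCore - length(posP)
        }
      }
      nLink <- nSites - nCore
      if (nLink > 0) {
        need <- nLink
        lposC <- character(0); lposP <- integer(0)
        for (try in 1:12) {
          if (need <= 0) break
          ch <- sample(names(chromLens), need, replace = TRUE,
                       prob = chromLens / totalLen)
          p <- as.integer(ceiling(runif(need) * chromLens[ch]))
          inLinker <- rep(FALSE, need)
          for (chrom in unique(ch)) {
            ii <- which(ch == chrom)
            dd <- dyadsByChrom[[chrom]]
            if (is.null(dd) || !length(dd)) { inLinker[ii] <- TRUE; next }
            nearest <- .nearestSortedDist(p[ii], dd)
            inLinker[ii] <- abs(nearest) > half
          }
          ok <- inLinker
          if (!is.null(genome)) {
            for (chrom in unique(ch[ok])) {
              ii <- which(ok & ch == chrom)
              ok[ii] <- isCG(chrom, p[ii])
            }
          }
          lposC <- c(lposC, ch[ok]); lposP <- c(lposP, p[ok])
          need <- nLink - length(lposP)
        }
        posC <- c(posC, lposC); posP <- c(posP, lposP)
      }
      if (length(posP)) {
        out[[cc]] <- data.frame(chrom = posC, pos = posP, context = cc,
                                stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) {
      return(GenomicRanges::GRanges(seqlengths = chromLens,
                                    context = character(0)))
    }
    df <- do.call(rbind, out)
    df <- unique(df)
    gr <- GenomicRanges::GRanges(df$chrom,
                                 IRanges::IRanges(df$pos, width = 1L),
                                 context = df$context,
                                 seqlengths = chromLens)
    sort(gr)
  })
}

# signed distance (pos - dyad) to the nearest element of sorted vector dd
.nearestSortedDist <- function(p, dd) {
  i <- findInterval(p, dd)
  lo <- pmax(i, 1L); hi <- pmin(i + 1L, length(dd))
  dLo <- p - dd[lo]; dHi <- p - dd[hi]
  # ties (equidistant) resolve to the downstream dyad => negative distance
  ifelse(i == 0L, dHi,
         ifelse(i >= length(dd), dLo,
                ifelse(abs(dHi) <= abs(dLo), dHi, dLo)))
}

#' Run the full generator
#'
#' Convenience wrapper producing every synthetic artifact from a single
#' configuration: genome, true nucleosomes, fragments, gene models, RNA
#' signal, feature annotations, methylation sites, and the truth bundle.
#'
#' @param config a \linkS4class{SimConfig}.
#' @param genomeCheckMethylation place methylation on C/G bases only
#'   (slower; default \code{FALSE} uses pure positional placement).
#' @return A named list of all generated artifacts.
#' @export
simulateDataset <- function(config = simConfig(),
                            genomeCheckMethylation = FALSE) {
  gg <- generateGenome(config)
  ann <- generateAnnotations(config)
  frags <- sampleFragments(gg$nucleosomes, config)
  meth <- generateMethylation(gg$nucleosomes, config,
                              genome = if (genomeCheckMethylation)
                                gg$genome else NULL)
  ann$truth$nucleosomes <- gg$nucleosomes
  list(config = config,
       genome = gg$genome,
       nucleosomes = gg$nucleosomes,
       fragments = frags,
       genes = ann$genes,
       rnaPlus = ann$rnaPlus, rnaMinus = ann$rnaMinus,
       tfbs = ann$tfbs, marks = ann$marks, states = ann$states,
       methylation = meth,
       truth = ann$truth)
}
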