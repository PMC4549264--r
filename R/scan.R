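# Enhancer-like nucleosome architecture scan: a depleted region between
# two well-positioned nucleosomes, themselves flanked by further
# well-positioned nucleosomes.  All scores are ratios, so hits are
# invariant under uniform scaling of the track.

#' Scan called nucleosomes for enhancer-like depleted-region patterns
#'
#' For each adjacent pair of called nucleosomes with both positioning
#' scores at least \code{posScoreMin}, an inter-dyad gap inside
#' \code{gapRange}, and a NOS minimum in the inter-core gap of at most
#' \code{troughFracMax} times the smaller summit: require at least
#' \code{minFlankSupport} additional nucleosomes with positioning score at
#' least \code{posScoreMin} within \code{flankSearchBp} on each outer
#' side.  A hit is emitted at the trough midpoint with
#' \code{score = mean(pair scores) * (1 - trough / min(summit))}; hits are
#' sorted by score and overlapping 200 bp windows are deduplicated keeping
#' the higher score.
#'
#' @param nucleosomes sorted \code{GRanges} from
#'   \code{\link{callNucleosomes}} (with \code{dyad}, \code{summitNos} and
#'   \code{positioningScore}).
#' @param track the \linkS4class{GenomeTrack} the calls came from.
#' @param config a \linkS4class{ScanConfig}.
#' @param windowBp emitted window width (default 200).
#' @return \code{GRanges} of hit windows with metadata \code{center},
#'   \code{leftDyad}, \code{rightDyad}, \code{flankSupport},
#'   \code{troughNos} and \code{score}, sorted by decreasing score.
#' @export
findPatterns <- function(nucleosomes, track, config = scanConfig(),
                         windowBp = 200L) {
  stopifnot(is(nucleosomes, "GRanges"), is(track, "GenomeTrack"),
            is(config, "ScanConfig"))
  validObject(config)
  hitsL <- list()
  chroms <- as.character(GenomicRanges::seqnames(nucleosomes))
  halfWin <- as.integer(windowBp) %/% 2L
  for (chrom in unique(chroms)) {
    nu <- nucleosomes[chroms == chrom]
    nu <- nu[order(nu$dyad)]
    if (length(nu) < 2) next
    v <- trackValues(track, chrom)
    d <- nu$dyad
    sc <- nu$positioningScore
    su <- nu$summitNos
    coreEnd <- GenomicRanges::end(nu)
    coreStart <- GenomicRanges::start(nu)
    for (i in seq_len(length(nu) - 1L)) {
      gap <- d[i + 1L] - d[i]
      if (gap < config@gapRange[1] || gap > config@gapRange[2]) next
      if (sc[i] < config@posScoreMin || sc[i + 1L] < config@posScoreMin) next
      gapLo <- coreEnd[i] + 1L
      gapHi <- coreStart[i + 1L] - 1L
      if (gapLo > gapHi) next
      trough <- min(v[gapLo:gapHi])
      minSummit <- min(su[i], su[i + 1L])
      if (minSummit <= 0 || trough > config@troughFracMax * minSummit) next
      # flank support on each outer side
      leftSup <- sum(d < d[i] & d >= d[i] - config@flankSearchBp &
                       sc >= config@posScoreMin)
      rightSup <- sum(d > d[i + 1L] & d <= d[i + 1L] + config@flankSearchBp &
                        sc >= config@posScoreMin)
      if (leftSup < config@minFlankSupport ||
          rightSup < config@minFlankSupport) next
      troughIdx <- gapLo:gapHi
      center <- as.integer(round(mean(troughIdx[v[troughIdx] == trough])))
      pairScore <- mean(c(sc[i], sc[i + 1L]))
      score <- pairScore * (1 - trough / minSummit)
      hitsL[[length(hitsL) + 1L]] <- data.frame(
        chrom = chrom, center = center,
        leftDyad = d[i], rightDyad = d[i + 1L],
        flankSupport = leftSup + rightSup,
        troughNos = trough, score = score)
    }
  }
  sl <- trackChromLengths(track)
  if (!length(hitsL)) {
    return(GenomicRanges::GRanges(
      center = integer(0), leftDyad = integer(0), rightDyad = integer(0),
      flankSupport = integer(0), troughNos = numeric(0), score = numeric(0)))
  }
  hits <- do.call(rbind, hitsL)
  hits <- hits[order(-hits$score), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    hits$chrom,
    IRanges::IRanges(hits$center - halfWin, width = as.integer(windowBp)),
    center = hits$center, leftDyad = hits$leftDyad,
    rightDyad = hits$rightDyad, flankSupport = hits$flankSupport,
    troughNos = hits$troughNos, score = hits$score,
    seqlengths = sl)
  # deduplicate overlapping windows, keeping the higher score
  keep <- rep(TRUE, length(gr))
  for (i in seq_along(gr)[-1]) {
    prior <- gr[which(keep[seq_len(i - 1L)])]
    if (length(prior) &&
        length(GenomicRanges::findOverlaps(gr[i], prior)) > 0) {
      keep[i] <- FALSE
    }
  }
  gr[keep]
}

#' Extract hit-window sequences for motif discovery
#'
#' Returns uppercase FASTA-ready sequences of fixed-size windows centred on
#' each hit, named \code{chrom:start-end} (0-based half-open, matching the
#' BED convention).  Windows extending past a chromosome end are dropped
#' with a message.
#'
#' @param genome named \code{DNAStringSet}.
#' @param hits \code{GRanges} from \code{\link{findPatterns}}.
#' @param size window size in bp (default 200).
#' @return Named \code{DNAStringSet} of length-\code{size} windows.
#' @export
extractHitSequences <- function(genome, hits, size = 200L) {
  stopifnot(is(genome, "DNAStringSet"), is(hits, "GRanges"))
  if (!length(hits)) return(Biostrings::DNAStringSet())
  half <- as.integer(size) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(hits))
  center <- hits$center
  if (is.null(center)) {
    center <- (GenomicRanges::start(hits) + GenomicRanges::end(hits)) %/% 2L
  }
  lens <- setNames(Biostrings::width(genome), names(genome))
  start <- center - half + 1L            # 1-based window [c-100, c+100)
  end <- start + as.integer(size) - 1L
  ok <- chrom %in% names(genome) & start >= 1L & end <= lens[chrom]
  if (any(!ok)) {
    message(sum(!ok), " hit window(s) outside chromosome bounds dropped")
  }
  if (!any(ok)) return(Biostrings::DNAStringSet())
  seqs <- vapply(which(ok), function(i) {
    toupper(substring(as.character(genome[[chrom[i]]]), start[i], end[i]))
  }, character(1))
  names(seqs) <- sprintf("%s:%d-%d", chrom[ok], start[ok] - 1L, end[ok])
  Biostrings::DNAStringSet(seqs)
}
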