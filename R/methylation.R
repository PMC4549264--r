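# Methylation--nucleosome geometry: per-nucleosome site counts with rank
# statistics, distance-to-dyad distributions, in-core methylation
# periodicity, methylation-centred occupancy, and the high-occupancy mCG
# subset.

.siteFrame <- function(sites) {
  if (is(sites, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
               pos = GenomicRanges::start(sites),
               context = if (!is.null(sites$context))
                 as.character(sites$context) else NA_character_,
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "pos") %in% names(sites)))
    as.data.frame(sites)
  }
}

#' Count methylation sites per called nucleosome
#'
#' A site belongs to a nucleosome iff its position lies within the core
#' interval (half-open on the BED scale; within \code{[start, end]} of the
#' 1-based closed core here).  Sites in linkers belong to no nucleosome;
#' with non-overlapping cores every site is assigned at most once.
#'
#' @param sites methylation sites: \code{GRanges} with a \code{context}
#'   column or \code{data.frame(chrom, pos, context)}.
#' @param nucleosomes \code{GRanges} from \code{\link{callNucleosomes}}.
#' @return Integer matrix, one row per nucleosome, one column per context.
#' @export
assignSitesToNucleosomes <- function(sites, nucleosomes) {
  stopifnot(is(nucleosomes, "GRanges"))
  ss <- .siteFrame(sites)
  ctxs <- sort(unique(ss$context))
  counts <- matrix(0L, length(nucleosomes), length(ctxs),
                   dimnames = list(names(nucleosomes), ctxs))
  if (!nrow(ss) || !length(nucleosomes)) return(counts)
  gr <- GenomicRanges::GRanges(ss$chrom, IRanges::IRanges(ss$pos, width = 1L))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, nucleosomes, ignore.strand = TRUE))
  if (length(ov)) {
    tab <- table(S4Vectors::subjectHits(ov),
                 ss$context[S4Vectors::queryHits(ov)])
    ri <- as.integer(rownames(tab))
    counts[ri, colnames(tab)] <- counts[ri, colnames(tab)] + as.matrix(tab)
  }
  counts
}

#' Occupancy stratified by per-nucleosome methylation count
#'
#' Nucleosomes are bucketed by the number of sites of one context they
#' contain (default buckets 0, 1, 2, 3, 4+); the mean core NOS per bucket
#' is compared by a Kruskal--Wallis test followed by all pairwise two-sided
#' Mann--Whitney--Wilcoxon tests with Bonferroni correction over the
#' pairwise family.
#'
#' @param nucleosomes \code{GRanges} with a \code{meanNos} column.
#' @param counts matrix from \code{\link{assignSitesToNucleosomes}}.
#' @param context context column to stratify on.
#' @param maxBucket counts >= this value are pooled into a "+" bucket
#'   (default 4).
#' @return List with \code{groups} (data.frame: label, n, meanNos),
#'   \code{kwP}, and \code{pairwise} (data.frame: groupA, groupB, rawP,
#'   bonferroniP).
#' @export
occupancyByCount <- function(nucleosomes, counts, context = "mCG",
                             maxBucket = 4L) {
  stopifnot(is(nucleosomes, "GRanges"), context %in% colnames(counts),
            length(nucleosomes) == nrow(counts))
  nos <- nucleosomes$meanNos
  if (is.null(nos)) stop("nucleosomes lack a 'meanNos' column")
  ct <- pmin(counts[, context], maxBucket)
  lab <- ifelse(ct >= maxBucket, paste0(maxBucket, "+"), as.character(ct))
  levs <- c(as.character(seq_len(maxBucket) - 1L), paste0(maxBucket, "+"))
  bucket <- factor(lab, levels = levs)
  present <- levels(bucket)[table(bucket) > 0]
  if (length(present) < 2) {
    stop("degenerate stratification: only bucket '", present,
         "' is non-empty")
  }
  bucket <- factor(as.character(bucket), levels = present)
  groups <- data.frame(
    label = present,
    n = as.integer(table(bucket)),
    meanNos = as.numeric(tapply(nos, bucket, mean)))
  kw <- kruskal.test(nos ~ bucket)
  pairs <- utils::combn(present, 2)
  m <- ncol(pairs)
  rawP <- vapply(seq_len(m), function(j) {
    # exact for small tie-free groups; normal approximation otherwise
    suppressWarnings(
      wilcox.test(nos[bucket == pairs[1, j]], nos[bucket == pairs[2, j]],
                  alternative = "two.sided")$p.value)
  }, numeric(1))
  list(groups = groups,
       kwP = kw$p.value,
       pairwise = data.frame(groupA = pairs[1, ], groupB = pairs[2, ],
                             rawP = rawP,
                             bonferroniP = pmin(1, rawP * m)))
}

#' Distance-to-nearest-dyad histogram of methylation sites
#'
#' Per site, the signed distance to the nearest dyad (positive = site
#' downstream of the dyad; equidistant ties resolve to the downstream dyad,
#' giving the negative distance).  Sites farther than \code{rangeBp} from
#' every dyad are excluded from the core view but counted.  Frequencies
#' are reported as percentages summing to 100 over the reported range.
#'
#' @param sites methylation sites (\code{GRanges} or data.frame).
#' @param dyads dyad positions: \code{GRanges} (uses its \code{dyad}
#'   column when present), or \code{data.frame(chrom, pos)}.
#' @param context restrict to one context (\code{NULL} = all sites).
#' @param rangeBp half-range of the histogram (default 73, the core view).
#' @return \code{data.frame(offset, count, frequencyPercent)} with
#'   attributes \code{nSites} (in range), \code{nTotal} and
#'   \code{context}.
#' @export
distanceToNearestDyad <- function(sites, dyads, context = NULL,
                                  rangeBp = 73L) {
  ss <- .siteFrame(sites)
  if (!is.null(context)) ss <- ss[ss$context %in% context, , drop = FALSE]
  dd <- .dyadPositions(dyads)
  if (!nrow(dd)) stop("no dyads supplied")
  dist <- rep(NA_real_, nrow(ss))
  for (chrom in unique(ss$chrom)) {
    dc <- sort(dd$pos[dd$chrom == chrom])
    ii <- which(ss$chrom == chrom)
    if (!length(dc)) next
    dist[ii] <- .nearestSortedDist(ss$pos[ii], dc)
  }
  offsets <- -rangeBp:rangeBp
  inRange <- !is.na(dist) & abs(dist) <= rangeBp
  counts <- tabulate(dist[inRange] + rangeBp + 1L,
                     nbins = 2L * rangeBp + 1L)
  n <- sum(counts)
  freq <- if (n > 0) 100 * counts / n else rep(0, length(counts))
  structure(
    data.frame(offset = offsets, count = counts, frequencyPercent = freq),
    nSites = n, nTotal = nrow(ss),
    context = if (is.null(context)) "all" else context)
}

#' Periodicity of in-core methylation frequencies
#'
#' Delegates to \code{\link{fftPeriodogram}} on the in-core frequency
#' vector of a distance histogram.
#'
#' @param hist result of \code{\link{distanceToNearestDyad}}.
#' @param band period band in bp (default [2, 20]).
#' @param ... passed to \code{\link{fftPeriodogram}}.
#' @return A \linkS4class{Periodogram}.
#' @export
methylationPeriodogram <- function(hist, band = c(2, 20), ...) {
  stopifnot(is.data.frame(hist), "frequencyPercent" %in% names(hist))
  fftPeriodogram(hist$frequencyPercent, band = band, ...)
}

#' Mean occupancy profile centred on methylation sites
#'
#' Strandless \code{\link{aggregateProfile}} around the sites of one
#' context.
#'
#' @param track \linkS4class{GenomeTrack} of NOS values.
#' @param sites methylation sites.
#' @param context restrict to one context (\code{NULL} = all).
#' @param flank half-window in bp (default 500).
#' @return Named numeric mean profile (names = offsets).
#' @export
methylationCenteredNOS <- function(track, sites, context = NULL,
                                   flank = 500L) {
  ss <- .siteFrame(sites)
  if (!is.null(context)) ss <- ss[ss$context %in% context, , drop = FALSE]
  if (!nrow(ss)) stop("no sites for the requested context")
  aggregateProfile(track, data.frame(chrom = ss$chrom, pos = ss$pos,
                                     strand = "*"), flank = flank)
}

#' Dyad-distance histogram of mCGs in high-occupancy nucleosomes
#'
#' The threshold defaults to the mean summit NOS of all called nucleosomes
#' (the dataset-specific analogue of a fixed published cutoff); the
#' histogram is computed from the mCG sites falling inside
#' strictly-above-threshold nucleosomes only, with distances measured to
#' those nucleosomes' dyads.
#'
#' @param sites methylation sites (mCG records are selected).
#' @param nucleosomes \code{GRanges} with \code{summitNos} and \code{dyad}
#'   columns.
#' @param threshold \code{"auto"} (mean summit NOS) or a number.
#' @param rangeBp half-range of the histogram (default 73).
#' @return As \code{\link{distanceToNearestDyad}}, with an extra
#'   \code{threshold} attribute.
#' @export
highOccupancySubset <- function(sites, nucleosomes, threshold = "auto",
                                rangeBp = 73L) {
  stopifnot(is(nucleosomes, "GRanges"))
  summit <- nucleosomes$summitNos
  if (is.null(summit)) stop("nucleosomes lack a 'summitNos' column")
  thr <- if (identical(threshold, "auto")) mean(summit)
         else as.numeric(threshold)
  high <- nucleosomes[summit > thr]
  if (!length(high)) stop("no nucleosomes above the occupancy threshold ",
                          signif(thr, 4))
  ss <- .siteFrame(sites)
  ss <- ss[ss$context == "mCG", , drop = FALSE]
  gr <- GenomicRanges::GRanges(ss$chrom, IRanges::IRanges(ss$pos, width = 1L))
  ov <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, high, ignore.strand = TRUE))
  ssIn <- ss[S4Vectors::queryHits(ov), , drop = FALSE]
  dyadIn <- high$dyad[S4Vectors::subjectHits(ov)]
  dist <- ssIn$pos - dyadIn
  offsets <- -rangeBp:rangeBp
  inRange <- abs(dist) <= rangeBp
  counts <- tabulate(dist[inRange] + rangeBp + 1L,
                     nbins = 2L * rangeBp + 1L)
  n <- sum(counts)
  freq <- if (n > 0) 100 * counts / n else rep(0, length(counts))
  structure(
    data.frame(offset = offsets, count = counts, frequencyPercent = freq),
    nSites = n, nTotal = nrow(ssIn), context = "mCG", threshold = thr)
}
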