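# Nucleosome occupancy score (NOS) maps and nucleosome calling.
#
# Conventions: fragments and nucleosomes are GRanges (1-based, closed, the
# native R convention; the BED readers/writers convert).  The inferred dyad
# of a fragment [start0, end0) in 0-based half-open coordinates is
# floor((start0 + end0 - 1) / 2) -- the midpoint, rounding down (leftward)
# for even-length fragments.  NOS(b) counts the dyad-centred cores
# [dyad - 73, dyad + 73] covering base b.

#' Collapse clonal (PCR duplicate) fragments
#'
#' Identical (chrom, start, end) triples are retained at most
#' \code{maxCopies} times, order-stably.
#'
#' @param fragments \code{GRanges} of fragment intervals.
#' @param maxCopies maximum copies of an identical interval to keep.
#' @return \code{GRanges} with clonal copies removed.
#' @examples
#' gr <- GenomicRanges::GRanges("c1", IRanges::IRanges(c(101, 101), c(250, 250)))
#' length(deduplicateFragments(gr))
#' @export
deduplicateFragments <- function(fragments, maxCopies = 1L) {
  stopifnot(is(fragments, "GRanges"), maxCopies >= 1)
  if (!length(fragments)) return(fragments)
  key <- paste(GenomicRanges::seqnames(fragments),
               GenomicRanges::start(fragments),
               GenomicRanges::end(fragments))
  copy <- stats::ave(seq_along(key), key, FUN = seq_along)
  fragments[copy <= maxCopies]
}

.fragmentDyads <- function(fragments) {
  # 0-based midpoint floor((start0 + end0 - 1)/2), returned 1-based
  s0 <- GenomicRanges::start(fragments) - 1L
  e0 <- GenomicRanges::end(fragments)
  (s0 + e0 - 1L) %/% 2L + 1L
}

#' Compute the per-base nucleosome occupancy score map
#'
#' Each fragment contributes its inferred dyad (midpoint, rounding down for
#' even lengths), extended to a \code{coreWidth} window centred on the dyad;
#' NOS(b) is the number of such cores covering base b.  Fragments whose
#' extended core is not fully inside the chromosome are rejected with a
#' warning (so the conservation identity
#' \code{sum(NOS) == coreWidth * acceptedFragments} holds exactly).
#'
#' @param fragments deduplicated \code{GRanges} of fragments.
#' @param chromSizes named vector of chromosome lengths; defaults to the
#'   \code{seqlengths} of \code{fragments}.
#' @param coreWidth odd core width in bp (default 147).
#' @return A raw-count \linkS4class{GenomeTrack}; the number of accepted
#'   fragments is stored in \code{metadata} as \code{acceptedFragments}.
#' @export
computeNOS <- function(fragments, chromSizes = NULL, coreWidth = 147L) {
  stopifnot(is(fragments, "GRanges"), coreWidth %% 2L == 1L)
  if (is.null(chromSizes)) {
    chromSizes <- GenomeInfoDb::seqlengths(fragments)
    if (!length(chromSizes) || anyNA(chromSizes)) {
      stop("supply 'chromSizes' or fragments with seqlengths")
    }
  }
  half <- (as.integer(coreWidth) - 1L) %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(fragments))
  unknown <- !(chrom %in% names(chromSizes))
  dyads <- .fragmentDyads(fragments)
  inBounds <- !unknown & dyads - half >= 1L &
    dyads + half <= chromSizes[chrom]
  nRej <- sum(!inBounds)
  if (nRej > 0) {
    warning(nRej, " fragment(s) outside chromosome bounds rejected")
  }
  chrom <- chrom[inBounds]; dyads <- dyads[inBounds]
  values <- lapply(names(chromSizes), function(cn) {
    L <- chromSizes[[cn]]
    d <- dyads[chrom == cn]
    delta <- numeric(L + 1L)
    if (length(d)) {
      add <- tabulate(d - half, nbins = L)
      sub <- tabulate(d + half + 1L, nbins = L + 1L)
      delta[seq_len(L)] <- add
      delta <- delta - sub
    }
    cumsum(delta)[seq_len(L)]
  })
  names(values) <- names(chromSizes)
  GenomeTrack(values, depthFactor = 1,
              metadata = list(acceptedFragments = sum(inBounds),
                              rejectedFragments = nRej,
                              coreWidth = as.integer(coreWidth)))
}

#' Normalize occupancy tracks to a common genome-wide mean
#'
#' Each dataset is linearly scaled so its genome-wide mean NOS equals
#' \code{targetMean}; the applied factor accumulates in \code{depthFactor}.
#' Normalizing an already normalized track is idempotent.
#'
#' @param tracks a single \linkS4class{GenomeTrack} or a list of them.
#' @param targetMean target genome-wide mean (default 100).
#' @return Track(s) of the same shape as the input.
#' @export
normalizeTracks <- function(tracks, targetMean = 100) {
  one <- function(tr) {
    m <- trackMean(tr)
    if (m == 0) stop("cannot normalize an all-zero track")
    f <- targetMean / m
    GenomeTrack(lapply(tr@values, function(v) v * f),
                depthFactor = tr@depthFactor * f, metadata = tr@metadata)
  }
  if (is(tracks, "GenomeTrack")) return(one(tracks))
  stopifnot(is.list(tracks), all(vapply(tracks, is, logical(1), "GenomeTrack")))
  lapply(tracks, one)
}

# Greedy plateau caller for one chromosome.  Candidate summits are the
# centres of maximal equal-value runs (a tied plateau proposes its centre,
# so a noiseless single-nucleosome plateau proposes its true dyad);
# candidates are taken highest-first (ties -> leftmost) and one is accepted
# unless it falls within minSpacing - 1 of an already accepted dyad;
# selection stops below minSummit.
.callChrom <- function(v, minSpacing, minSummit) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values >= minSummit
  if (!any(keep)) return(integer(0))
  cand <- (starts[keep] + ends[keep]) %/% 2L
  val <- r$values[keep]
  ord <- order(-val, cand)
  blocked <- logical(length(v))
  dyads <- integer(0)
  for (d in cand[ord]) {
    if (blocked[d]) next
    dyads <- c(dyads, d)
    lo <- max(1L, d - minSpacing + 1L)
    hi <- min(length(v), d + minSpacing - 1L)
    blocked[lo:hi] <- TRUE
  }
  sort(dyads)
}

#' Call nucleosomes from an occupancy track
#'
#' Greedy summit selection: repeatedly take the highest remaining base as a
#' dyad (a tied plateau calls the centre of its leftmost maximal run), emit
#' the 147 bp core around it, and exclude all bases closer than
#' \code{minSpacing} to a called dyad from further selection; stop when the
#' remaining maximum falls below \code{minSummit}.  Consecutive called dyads
#' are therefore never closer than \code{minSpacing} bp.
#'
#' @param track a \linkS4class{GenomeTrack} (raw or normalized).
#' @param minSpacing minimum inter-dyad distance in bp (default 150; values
#'   below 147 give overlapping cores and raise a warning).
#' @param minSummit minimum summit NOS to call (default 1).
#' @param coreWidth odd core width (default 147).
#' @param bgFlank background flank used for the positioning score (bp).
#' @return Sorted \code{GRanges} of \code{coreWidth} cores with metadata
#'   \code{dyad}, \code{summitNos}, \code{meanNos} and
#'   \code{positioningScore}.
#' @export
callNucleosomes <- function(track, minSpacing = 150L, minSummit = 1,
                            coreWidth = 147L, bgFlank = 500L) {
  stopifnot(is(track, "GenomeTrack"), coreWidth %% 2L == 1L)
  if (minSpacing < coreWidth) {
    warning("minSpacing < core width: called cores may overlap")
  }
  half <- (as.integer(coreWidth) - 1L) %/% 2L
  out <- list()
  for (chrom in names(track@values)) {
    v <- track@values[[chrom]]
    dyads <- .callChrom(v, as.integer(minSpacing), minSummit)
    # cores must lie inside the chromosome
    dyads <- dyads[dyads - half >= 1L & dyads + half <= length(v)]
    if (!length(dyads)) next
    cs <- cumsum(c(0, v))
    coreSum <- cs[dyads + half + 1L] - cs[dyads - half]
    summit <- v[dyads]
    pscore <- .positioningScoreVec(v, dyads, summit, half, bgFlank, cs)
    out[[chrom]] <- data.frame(
      chrom = chrom, dyad = dyads, summitNos = summit,
      meanNos = coreSum / coreWidth, positioningScore = pscore)
  }
  if (!length(out)) {
    return(GenomicRanges::GRanges(dyad = integer(0), summitNos = numeric(0),
                                  meanNos = numeric(0),
                                  positioningScore = numeric(0)))
  }
  df <- do.call(rbind, unname(out))
  sl <- trackChromLengths(track)
  gr <- GenomicRanges::GRanges(
    factor(df$chrom, levels = names(sl)),
    IRanges::IRanges(df$dyad - half, df$dyad + half),
    dyad = df$dyad, summitNos = df$summitNos, meanNos = df$meanNos,
    positioningScore = df$positioningScore,
    seqlengths = sl)
  gr <- sort(gr)
  names(gr) <- sprintf("nuc%d", seq_along(gr))
  gr
}

# positioning score = summit / mean NOS over [d - bgFlank, d + bgFlank]
# excluding the core; zero background => +Inf sentinel
.positioningScoreVec <- function(v, dyads, summit, half, bgFlank, cs = NULL) {
  if (is.null(cs)) cs <- cumsum(c(0, v))
  L <- length(v)
  lo <- pmax(1L, dyads - as.integer(bgFlank))
  hi <- pmin(L, dyads + as.integer(bgFlank))
  cLo <- pmax(1L, dyads - half)
  cHi <- pmin(L, dyads + half)
  winSum <- cs[hi + 1L] - cs[lo]
  coreSum <- cs[cHi + 1L] - cs[cLo]
  n <- (hi - lo + 1L) - (cHi - cLo + 1L)
  bg <- (winSum - coreSum) / pmax(n, 1L)
  ifelse(bg == 0, Inf, summit / bg)
}

#' Positioning score of called nucleosomes
#'
#' Summit NOS divided by the mean NOS in a \code{bgFlank} window around the
#' dyad, excluding the core itself (truncated at chromosome ends).  A zero
#' background yields \code{Inf}, ranked above all finite scores.
#'
#' @param nucleosomes \code{GRanges} from \code{\link{callNucleosomes}}.
#' @param track the \linkS4class{GenomeTrack} the calls came from.
#' @param bgFlank background half-window in bp (default 500).
#' @param coreWidth odd core width (default 147).
#' @return Numeric vector of dimensionless scores.
#' @export
positioningScore <- function(nucleosomes, track, bgFlank = 500L,
                             coreWidth = 147L) {
  stopifnot(is(nucleosomes, "GRanges"), is(track, "GenomeTrack"))
  half <- (as.integer(coreWidth) - 1L) %/% 2L
  res <- numeric(length(nucleosomes))
  chroms <- as.character(GenomicRanges::seqnames(nucleosomes))
  for (chrom in unique(chroms)) {
    ii <- which(chroms == chrom)
    v <- trackValues(track, chrom)
    d <- nucleosomes$dyad[ii]
    if (is.null(d)) d <- GenomicRanges::start(nucleosomes)[ii] + half
    res[ii] <- .positioningScoreVec(v, d, v[d], half, bgFlank)
  }
  res
}

#' Masked, binned Pearson correlation of two occupancy maps
#'
#' Masked bases are dropped; the remaining bases are averaged in fixed
#' genomic windows of \code{bin} bp, and the Pearson correlation over the
#' concatenated bins (shared by both tracks) is returned.
#'
#' @param trackA,trackB \linkS4class{GenomeTrack}s over the same chromosomes.
#' @param bin window width in bp (default 10).
#' @param mask optional \code{GRanges} of regions to exclude.
#' @return Pearson correlation coefficient in [-1, 1].
#' @export
binnedPCC <- function(trackA, trackB, bin = 10L, mask = NULL) {
  stopifnot(is(trackA, "GenomeTrack"), is(trackB, "GenomeTrack"), bin >= 1)
  if (!identical(sort(names(trackA@values)), sort(names(trackB@values)))) {
    stop("tracks cover different chromosome sets")
  }
  binsA <- numeric(0); binsB <- numeric(0)
  for (chrom in names(trackA@values)) {
    a <- trackA@values[[chrom]]
    b <- trackB@values[[chrom]]
    if (length(a) != length(b)) stop("chromosome length mismatch: ", chrom)
    use <- rep(TRUE, length(a))
    if (!is.null(mask)) {
      mk <- mask[as.character(GenomicRanges::seqnames(mask)) == chrom]
      for (j in seq_along(mk)) {
        lo <- max(1L, GenomicRanges::start(mk)[j])
        hi <- min(length(a), GenomicRanges::end(mk)[j])
        if (lo <= hi) use[lo:hi] <- FALSE
      }
    }
    if (!any(use)) next
    idx <- which(use)
    binId <- (idx - 1L) %/% as.integer(bin)
    binsA <- c(binsA, as.numeric(tapply(a[idx], binId, mean)))
    binsB <- c(binsB, as.numeric(tapply(b[idx], binId, mean)))
  }
  if (length(binsA) < 2) stop("fewer than 2 usable bins")
  if (stats::sd(binsA) == 0 || stats::sd(binsB) == 0) {
    stop("zero variance: correlation undefined")
  }
  cor(binsA, binsB)
}
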