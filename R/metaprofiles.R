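# Strand-aware aggregation of occupancy around genomic features, RNA-Signal
# construction, expression stratification, clustering of TSS architectures,
# +1-nucleosome shifts, and active-site filtering.

#' Combine stranded RNA tracks into a total RNA-Signal
#'
#' Each strand is normalized to an equal total signal (the mean of the
#' non-zero strand totals) and the per-base values are added.  A strand
#' with zero total contributes zero and does not rescale the other.
#'
#' @param plusTrack,minusTrack \linkS4class{GenomeTrack}s over the same
#'   chromosomes.
#' @return A combined \linkS4class{GenomeTrack}.
#' @export
buildRnaSignal <- function(plusTrack, minusTrack) {
  stopifnot(is(plusTrack, "GenomeTrack"), is(minusTrack, "GenomeTrack"))
  if (!identical(sort(names(plusTrack@values)),
                 sort(names(minusTrack@values)))) {
    stop("strand tracks cover different chromosome sets")
  }
  tp <- sum(vapply(plusTrack@values, sum, numeric(1)))
  tm <- sum(vapply(minusTrack@values, sum, numeric(1)))
  tot <- c(tp, tm)
  nz <- tot > 0
  target <- if (any(nz)) mean(tot[nz]) else 0
  fp <- if (tp > 0) target / tp else 0
  fm <- if (tm > 0) target / tm else 0
  values <- lapply(names(plusTrack@values), function(chrom) {
    p <- plusTrack@values[[chrom]]
    m <- minusTrack@values[[chrom]]
    if (length(p) != length(m)) stop("chromosome length mismatch: ", chrom)
    p * fp + m * fm
  })
  names(values) <- names(plusTrack@values)
  GenomeTrack(values, metadata = list(plusFactor = fp, minusFactor = fm))
}

#' Total expression of genes from a combined RNA signal
#'
#' Sum of the combined signal over each gene span (strand-agnostic).
#'
#' @param genes \code{GRanges} of gene models.
#' @param rna combined \linkS4class{GenomeTrack} from
#'   \code{\link{buildRnaSignal}}.
#' @return Named numeric vector (names from \code{genes$name} when
#'   present).
#' @export
totalExpression <- function(genes, rna) {
  stopifnot(is(genes, "GRanges"), is(rna, "GenomeTrack"))
  res <- numeric(length(genes))
  chroms <- as.character(GenomicRanges::seqnames(genes))
  for (chrom in unique(chroms)) {
    v <- trackValues(rna, chrom)
    cs <- cumsum(c(0, v))
    ii <- which(chroms == chrom)
    lo <- pmax(1L, GenomicRanges::start(genes)[ii])
    hi <- pmin(length(v), GenomicRanges::end(genes)[ii])
    res[ii] <- ifelse(hi >= lo, cs[hi + 1L] - cs[lo], 0)
  }
  if (!is.null(genes$name)) names(res) <- genes$name
  res
}

#' Split values into expression quartiles
#'
#' Quartiles are assigned by rank (ties broken by stable input order), so
#' all-equal inputs split into equal quarters in input order.
#'
#' @param values numeric vector (length >= 4).
#' @return Factor with levels Q1 (lowest) .. Q4 (highest).
#' @examples
#' quartileSplit(0:7)
#' @export
quartileSplit <- function(values) {
  n <- length(values)
  if (n < 4) stop("need at least 4 values for quartiles")
  r <- rank(values, ties.method = "first")
  q <- ceiling(4 * r / n)
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

#' Identify transcriptionally silent genes
#'
#' A gene is silent iff the mean combined RNA signal over its span extended
#' by \code{flank} bp on both sides is at most \code{eps}.
#'
#' @param genes \code{GRanges} of gene models.
#' @param rna combined \linkS4class{GenomeTrack}.
#' @param eps silence threshold on the mean signal (default 0).
#' @param flank extension in bp (default 500).
#' @return Named logical vector.
#' @export
classifySilent <- function(genes, rna, eps = 0, flank = 500L) {
  stopifnot(eps >= 0)
  res <- logical(length(genes))
  chroms <- as.character(GenomicRanges::seqnames(genes))
  for (chrom in unique(chroms)) {
    v <- trackValues(rna, chrom)
    cs <- cumsum(c(0, v))
    ii <- which(chroms == chrom)
    lo <- pmax(1L, GenomicRanges::start(genes)[ii] - flank)
    hi <- pmin(length(v), GenomicRanges::end(genes)[ii] + flank)
    res[ii] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L) <= eps
  }
  if (!is.null(genes$name)) names(res) <- genes$name
  res
}

.featureFrame <- function(features) {
  if (is(features, "GRanges")) {
    pos <- if (!is.null(features$tss)) features$tss
           else GenomicRanges::start(features)
    data.frame(chrom = as.character(GenomicRanges::seqnames(features)),
               pos = pos,
               strand = as.character(GenomicRanges::strand(features)),
               name = if (!is.null(features$name)) features$name
                      else paste0("f", seq_along(features)),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("chrom", "pos") %in% names(features)))
    data.frame(chrom = features$chrom, pos = features$pos,
               strand = if ("strand" %in% names(features)) features$strand
                        else "*",
               name = if ("name" %in% names(features)) features$name
                      else paste0("f", seq_len(nrow(features))),
               stringsAsFactors = FALSE)
  }
}

#' Feature-centred profile matrix
#'
#' One row per usable feature: the track values over \code{pos - flank ..
#' pos + flank}.  Rows of minus-strand features are reversed so positive
#' offsets point downstream in transcription direction.  Features closer
#' than \code{flank} to a chromosome boundary are dropped and counted.
#'
#' @param track a \linkS4class{GenomeTrack}.
#' @param features \code{GRanges} (position = \code{tss} column when
#'   present, else start; strand honoured) or
#'   \code{data.frame(chrom, pos[, strand, name])}.
#' @param flank half-window F in bp; offsets are -F..+F.
#' @return Matrix with feature names as rownames, offsets as colnames, and
#'   attribute \code{nDropped}.
#' @export
profileMatrix <- function(track, features, flank = 1000L) {
  stopifnot(is(track, "GenomeTrack"), flank >= 1)
  ff <- .featureFrame(features)
  lens <- trackChromLengths(track)
  known <- ff$chrom %in% names(lens)
  usable <- known & ff$pos - flank >= 1 & ff$pos + flank <= lens[ff$chrom]
  nDropped <- sum(!usable)
  ff <- ff[usable, , drop = FALSE]
  if (!nrow(ff)) stop("no usable features (all dropped at boundaries)")
  offs <- -flank:flank
  mat <- matrix(NA_real_, nrow(ff), length(offs),
                dimnames = list(ff$name, offs))
  for (chrom in unique(ff$chrom)) {
    v <- track@values[[chrom]]
    ii <- which(ff$chrom == chrom)
    for (i in ii) {
      row <- v[(ff$pos[i] - flank):(ff$pos[i] + flank)]
      if (ff$strand[i] == "-") row <- rev(row)
      mat[i, ] <- row
    }
  }
  structure(mat, nDropped = nDropped)
}

#' Mean feature-centred profile
#'
#' Column means of \code{\link{profileMatrix}}: the strand-aware average
#' track signal around the features.
#'
#' @inheritParams profileMatrix
#' @return Named numeric vector (names = offsets) with attributes
#'   \code{nUsed} and \code{nDropped}.
#' @export
aggregateProfile <- function(track, features, flank = 1000L) {
  mat <- profileMatrix(track, features, flank)
  structure(colMeans(mat), names = colnames(mat),
            nUsed = nrow(mat), nDropped = attr(mat, "nDropped"))
}

#' Reference-normalized mean profile
#'
#' Per gene, \code{ratio(p) = (A(p) + pseudo) / (REF(p) + pseudo)}, then
#' averaged over genes.  Quantifies how e.g. transcription changes a
#' sequence-driven occupancy ground state measured by the reference.
#'
#' @param profA,profRef matched per-gene profile matrices (same offsets;
#'   genes matched by rowname, unmatched rows dropped with a warning).
#' @param pseudo pseudocount on the normalized scale (default 1).
#' @return Named numeric vector of mean ratios per offset.
#' @export
normalizeByReference <- function(profA, profRef, pseudo = 1) {
  stopifnot(is.matrix(profA), is.matrix(profRef),
            ncol(profA) == ncol(profRef))
  common <- intersect(rownames(profA), rownames(profRef))
  nDrop <- nrow(profA) - length(common)
  if (nDrop > 0) {
    warning(nDrop, " gene(s) missing from the reference were dropped")
  }
  if (!length(common)) stop("no genes shared between profiles")
  ratio <- (profA[common, , drop = FALSE] + pseudo) /
    (profRef[common, , drop = FALSE] + pseudo)
  structure(colMeans(ratio), names = colnames(profA))
}

#' k-means clustering of feature-centred profiles
#'
#' Each row is scaled by its own maximum (so cluster structure reflects
#' architecture, not amplitude) before Euclidean k-means with
#' \code{nInit} restarts under a fixed seed.  All-zero rows are dropped
#' with a warning.
#'
#' @param mat profile matrix from \code{\link{profileMatrix}}.
#' @param k number of clusters (default 10).
#' @param nInit random restarts (default 10).
#' @param seed RNG seed.
#' @param iterMax maximum k-means iterations.
#' @return List with \code{k}, \code{assignments} (named integer vector),
#'   \code{centroids} (k x offsets matrix of scaled means), and
#'   \code{maxNosLocation}: per cluster, the offset of the centroid
#'   maximum.
#' @export
kmeansProfiles <- function(mat, k = 10L, nInit = 10L, seed = 1L,
                           iterMax = 100L) {
  stopifnot(is.matrix(mat))
  rowMax <- apply(mat, 1, max)
  if (any(rowMax == 0)) {
    warning(sum(rowMax == 0), " all-zero profile row(s) dropped")
    mat <- mat[rowMax > 0, , drop = FALSE]
    rowMax <- rowMax[rowMax > 0]
  }
  if (nrow(mat) < k) stop("fewer usable rows than clusters")
  scaled <- mat / rowMax
  km <- .withSeed(seed, kmeans(scaled, centers = k, nstart = nInit,
                               iter.max = iterMax))
  offsets <- as.integer(colnames(mat))
  maxLoc <- offsets[apply(km$centers, 1, which.max)]
  list(k = as.integer(k),
       assignments = setNames(km$cluster, rownames(scaled)),
       centroids = km$centers,
       maxNosLocation = maxLoc)
}

.movingAverage <- function(x, w) {
  if (w <= 1) return(x)
  k <- rep(1 / w, w)
  y <- stats::filter(x, k, sides = 2)
  as.numeric(ifelse(is.na(y), x, y))
}

.firstLocalMax <- function(prof, offsets, window) {
  inWin <- offsets > window[1] & offsets <= window[2]
  idx <- which(inWin)
  for (i in idx) {
    lo <- if (i > 1) prof[i - 1] else -Inf
    hi <- if (i < length(prof)) prof[i + 1] else -Inf
    if (prof[i] > lo && prof[i] >= hi) return(offsets[i])
  }
  NA_integer_
}

#' +1-nucleosome shift between two TSS profiles
#'
#' The +1 location of an oriented TSS profile is the offset of the first
#' local maximum downstream of the TSS (within \code{search}), after
#' moving-average smoothing of width \code{smooth} bp.  The shift is
#' \code{location(B) - location(A)} (positive = B's +1 sits further
#' downstream).
#'
#' @param profileA,profileB named numeric profiles (names = offsets, TSS at
#'   offset 0), e.g. from \code{\link{aggregateProfile}}.
#' @param search window (bp downstream of the TSS) searched for the first
#'   local maximum (default (0, 300]).
#' @param smooth moving-average width in bp (default 5).
#' @return List with \code{shift}, \code{locationA}, \code{locationB} and
#'   the smoothing width used.
#' @export
plusOneShift <- function(profileA, profileB, search = c(0, 300),
                         smooth = 5L) {
  offA <- as.integer(names(profileA))
  offB <- as.integer(names(profileB))
  if (is.null(offA) || is.null(offB)) stop("profiles must be offset-named")
  la <- .firstLocalMax(.movingAverage(as.numeric(profileA), smooth),
                       offA, search)
  lb <- .firstLocalMax(.movingAverage(as.numeric(profileB), smooth),
                       offB, search)
  if (is.na(la) || is.na(lb)) {
    stop("no local maximum found in (", search[1], ", ", search[2], "]")
  }
  list(shift = lb - la, locationA = la, locationB = lb,
       smooth = as.integer(smooth))
}

#' Filter feature sites for active chromatin
#'
#' A site is active iff its mean accessibility (e.g. DNase) signal is at or
#' above the \code{qAccess} quantile of per-site means AND its mean NOS is
#' at or below the \code{qNos} quantile of per-site means (both thresholds
#' inclusive, so a single site passes trivially).
#'
#' @param sites \code{GRanges} of candidate sites (e.g. TFBS).
#' @param accessTrack,nosTrack \linkS4class{GenomeTrack}s covering the
#'   sites.
#' @param qAccess accessibility quantile threshold (default 0.75).
#' @param qNos occupancy quantile threshold (default 0.25).
#' @return The active subset of \code{sites}, with \code{accessMean} and
#'   \code{nosMean} metadata columns.
#' @export
activeSiteFilter <- function(sites, accessTrack, nosTrack,
                             qAccess = 0.75, qNos = 0.25) {
  stopifnot(is(sites, "GRanges"))
  if (!length(sites)) return(sites)
  siteMean <- function(track) {
    res <- numeric(length(sites))
    chroms <- as.character(GenomicRanges::seqnames(sites))
    for (chrom in unique(chroms)) {
      v <- trackValues(track, chrom)
      cs <- cumsum(c(0, v))
      ii <- which(chroms == chrom)
      lo <- pmax(1L, GenomicRanges::start(sites)[ii])
      hi <- pmin(length(v), GenomicRanges::end(sites)[ii])
      res[ii] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
    }
    res
  }
  am <- siteMean(accessTrack)
  nm <- siteMean(nosTrack)
  active <- am >= quantile(am, qAccess) & nm <= quantile(nm, qNos)
  out <- sites[active]
  out$accessMean <- am[active]
  out$nosMean <- nm[active]
  out
}
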