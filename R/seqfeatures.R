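# Dyad-relative sequence composition of the nucleosome core particle and
# FFT-based periodicity estimation.

.MONO <- c("A", "C", "G", "T")
.DI <- as.vector(outer(.MONO, .MONO, paste0))

.dyadPositions <- function(dyads) {
  if (is(dyads, "GRanges")) {
    data.frame(chrom = as.character(GenomicRanges::seqnames(dyads)),
               pos = if (!is.null(dyads$dyad)) dyads$dyad
                     else GenomicRanges::start(dyads),
               stringsAsFactors = FALSE)
  } else if (is.data.frame(dyads)) {
    stopifnot(all(c("chrom", "pos") %in% names(dyads)))
    dyads[c("chrom", "pos")]
  } else {
    stop("'dyads' must be a GRanges or a data.frame(chrom, pos)")
  }
}

#' Dyad-relative mono- or dinucleotide frequency profiles
#'
#' For each mono- (\code{k = 1}) or dinucleotide (\code{k = 2}), the value
#' at offset p is the fraction of sites whose base (or base pair starting)
#' at dyad + p matches, for offsets -73..+73 relative to the dyad.  Sites
#' without 73 bp of sequence on both sides are skipped (and counted);
#' dinucleotides at offset +73 read one base past the core edge and sites
#' lacking that base are skipped for that offset only.
#'
#' @param genome named \code{DNAStringSet}.
#' @param dyads \code{GRanges} of dyad positions (width-1 ranges, or called
#'   nucleosomes carrying a \code{dyad} column) or a
#'   \code{data.frame(chrom, pos)} with 1-based positions.
#' @param k 1 (mononucleotides) or 2 (dinucleotides).
#' @param half core half-width (default 73).
#' @return Numeric matrix (4 or 16 rows, labelled; one column per offset,
#'   colnames -73..73) with attributes \code{nSites} (usable sites) and
#'   \code{nSkipped}.
#' @examples
#' genome <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100),
#'                                                   collapse = "")))
#' prof <- dyadRelativeFrequency(genome,
#'   data.frame(chrom = "chr1", pos = c(150, 200)), k = 1)
#' prof[, "0"]
#' @export
dyadRelativeFrequency <- function(genome, dyads, k = 2, half = 73L) {
  stopifnot(is(genome, "DNAStringSet"), k %in% c(1, 2))
  dd <- .dyadPositions(dyads)
  chromLens <- setNames(Biostrings::width(genome), names(genome))
  known <- dd$chrom %in% names(genome)
  usable <- known & dd$pos - half >= 1 & dd$pos + half <= chromLens[dd$chrom]
  nSkipped <- sum(!usable)
  dd <- dd[usable, , drop = FALSE]
  if (!nrow(dd)) stop("no usable dyads (all sites skipped)")
  offsets <- -half:half
  width <- length(offsets)
  labels <- if (k == 1) .MONO else .DI
  counts <- matrix(0L, nrow = length(labels), ncol = width,
                   dimnames = list(labels, offsets))
  denom <- integer(width)
  for (chrom in unique(dd$chrom)) {
    pos <- dd$pos[dd$chrom == chrom]
    seqStr <- as.character(genome[[chrom]])
    L <- chromLens[[chrom]]
    hasExtra <- pos + half + 1L <= L
    for (grp in c(TRUE, FALSE)) {
      p <- pos[hasExtra == grp]
      if (!length(p)) next
      wlen <- width + as.integer(k == 2 && grp)
      ws <- substring(seqStr, p - half, p - half + wlen - 1L)
      nOff <- if (k == 1) width else (wlen - 1L)
      for (j in seq_len(nOff)) {
        token <- substr(ws, j, j + k - 1L)
        tab <- table(factor(token, levels = labels))
        counts[, j] <- counts[, j] + as.integer(tab)
        denom[j] <- denom[j] + length(p)
      }
    }
  }
  keep <- denom > 0
  freq <- counts
  freq[, keep] <- sweep(counts[, keep, drop = FALSE], 2, denom[keep], `/`)
  freq[, !keep] <- NA_real_
  structure(freq, nSites = nrow(dd), nSkipped = nSkipped, k = k)
}

#' FFT periodogram of a positional profile
#'
#' The profile is mean-subtracted, zero-padded to \code{padTo}, and
#' Fourier-transformed; power is the squared magnitude.  The dominant
#' period is 1/frequency of the maximum in-band power, refined by quadratic
#' interpolation around the peak bin.  No dominant period is reported when
#' the peak power is below \code{minPeakRatio} times the median in-band
#' power, or when the in-band maximum sits at a band edge without being a
#' local maximum of the full spectrum (a smoothly decaying spectrum has no
#' true peak).
#'
#' @param values numeric positional profile (e.g. one row of
#'   \code{\link{dyadRelativeFrequency}}), length >= 16.
#' @param band period search band in bp (default [2, 20]).
#' @param padTo zero-padding length (default 1024).
#' @param minPeakRatio significance threshold: peak power over median
#'   in-band power (default 4).
#' @return A \linkS4class{Periodogram}.
#' @examples
#' p <- -73:73
#' fftPeriodogram(cos(2 * pi * p / 10))
#' @export
fftPeriodogram <- function(values, band = c(2, 20), padTo = 1024L,
                           minPeakRatio = 4) {
  values <- as.numeric(values)
  if (anyNA(values)) values <- values[!is.na(values)]
  n <- length(values)
  if (n < 16) stop("profile too short (need >= 16 values)")
  if (band[1] < 2 || band[2] > n) {
    stop("band [", band[1], ", ", band[2], "] outside the resolvable ",
         "range [2, ", n, "] bp")
  }
  N <- max(as.integer(padTo), n)
  x <- c(values - mean(values), rep(0, N - n))
  X <- fft(x)
  j <- seq_len(N %/% 2L)          # positive frequencies
  power <- Mod(X[j + 1L])^2
  freq <- j / N
  inBand <- freq >= 1 / band[2] & freq <= 1 / band[1]
  if (!any(inBand)) stop("band contains no frequency bins; increase padTo")
  bandIdx <- which(inBand)
  pg <- function(dp, ratio) new("Periodogram",
    periods = rev(1 / freq[bandIdx]), power = rev(power[bandIdx]),
    band = as.numeric(band), dominantPeriod = dp, peakRatio = ratio)
  pk <- bandIdx[which.max(power[bandIdx])]
  med <- median(power[bandIdx])
  if (power[pk] <= 0 || med <= 0) return(pg(NA_real_, NA_real_))
  ratio <- power[pk] / med
  if (ratio < minPeakRatio) return(pg(NA_real_, ratio))
  atEdge <- pk == bandIdx[1] || pk == bandIdx[length(bandIdx)]
  if (atEdge) {
    lo <- if (pk > 1) power[pk - 1L] else 0
    hi <- if (pk < length(power)) power[pk + 1L] else 0
    if (power[pk] < lo || power[pk] < hi) return(pg(NA_real_, ratio))
  }
  delta <- 0
  if (pk > 1 && pk < length(power)) {
    den <- power[pk - 1L] - 2 * power[pk] + power[pk + 1L]
    if (den < 0) delta <- 0.5 * (power[pk - 1L] - power[pk + 1L]) / den
    delta <- max(-0.5, min(0.5, delta))
  }
  dp <- N / (pk + delta)
  dp <- max(band[1], min(band[2], dp))
  pg(dp, ratio)
}

#' Genome-wide nucleosome phasing spectrum
#'
#' Samples uniform windows from an occupancy track, averages the
#' autocorrelation of the mean-centred NOS over lags up to
#' \code{windowBp / 2}, and Fourier-transforms the mean autocorrelation.
#' The dominant period within \code{band} (default 120--300 bp) is the
#' nucleosome repeat length; unphased (e.g. nucleosomes at random
#' positions) tracks report none.
#'
#' @param track a \linkS4class{GenomeTrack}.
#' @param nWindows number of windows to sample (default 200).
#' @param windowBp window width in bp (default 2000; must not exceed the
#'   chromosome length).
#' @param seed RNG seed for window sampling.
#' @param band period band in bp (default [120, 300]).
#' @param padTo zero-padding for the spectrum (default 8192).
#' @param minPeakRatio significance threshold (default 4).
#' @return A \linkS4class{Periodogram}; \code{dominantPeriod} is the
#'   estimated nucleosome repeat length or \code{NA}.
#' @export
phasingPeriodogram <- function(track, nWindows = 200L, windowBp = 2000L,
                               seed = 1L, band = c(120, 300),
                               padTo = 8192L, minPeakRatio = 4) {
  stopifnot(is(track, "GenomeTrack"))
  lens <- trackChromLengths(track)
  ok <- lens >= windowBp
  if (!any(ok)) stop("windowBp exceeds every chromosome length")
  lens <- lens[ok]
  .withSeed(seed, {
    chromPick <- sample(names(lens), nWindows, replace = TRUE,
                        prob = lens / sum(lens))
    lagMax <- as.integer(windowBp %/% 2L)
    acSum <- numeric(lagMax + 1L)
    nUsed <- 0L
    for (w in seq_len(nWindows)) {
      chrom <- chromPick[w]
      v <- track@values[[chrom]]
      s <- sample.int(length(v) - windowBp + 1L, 1L)
      win <- v[s:(s + windowBp - 1L)]
      if (stats::sd(win) == 0) next    # degenerate window
      ac <- as.numeric(acf(win, lag.max = lagMax, plot = FALSE,
                           demean = TRUE)$acf)
      acSum <- acSum + ac
      nUsed <- nUsed + 1L
    }
    if (nUsed == 0L) stop("all sampled windows were degenerate (constant)")
    fftPeriodogram(acSum / nUsed, band = band, padTo = padTo,
                   minPeakRatio = minPeakRatio)
  })
}
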