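# Plain-text genome-track and interval IO.  BED and bedGraph are 0-based
# half-open on disk and converted to the 1-based closed GRanges convention
# in memory; fixedStep wiggle is 1-based.  Readers raise errors with
# file:line context on malformed input; writers emit canonical files so
# that write(read(x)) is byte-identical for canonical inputs.

.ioStop <- function(path, line, msg) {
  stop(path, ":", line, ": ", msg, call. = FALSE)
}

#' Read a chrom.sizes file
#'
#' @param path two-column TSV (chrom, length).
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, integer(1)) < 2)
  if (length(bad)) .ioStop(path, bad[1], "expected two tab-separated fields")
  lens <- suppressWarnings(as.integer(vapply(parts, `[`, character(1), 2)))
  if (anyNA(lens)) {
    .ioStop(path, which(is.na(lens))[1], "chromosome length is not a number")
  }
  setNames(lens, vapply(parts, `[`, character(1), 1))
}

#' @rdname readChromSizes
#' @param chromSizes named vector of chromosome lengths.
#' @export
writeChromSizes <- function(chromSizes, path) {
  writeLines(paste(names(chromSizes), chromSizes, sep = "\t"), path)
  invisible(path)
}

.parseBedLines <- function(path, minCols) {
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "track") &
    !startsWith(lines, "#")
  lineNo <- which(keep)
  parts <- strsplit(lines[keep], "\t")
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < minCols)) {
    .ioStop(path, lineNo[which(ncols < minCols)[1]],
            paste("expected at least", minCols, "fields"))
  }
  list(parts = parts, lineNo = lineNo)
}

#' Read BED intervals (BED3/BED6) as GRanges
#'
#' 0-based half-open records become 1-based closed ranges.  Records with
#' \code{start >= end} are rejected with the offending file:line.
#'
#' @param path BED file.
#' @param chromSizes optional named lengths to attach as seqlengths.
#' @return \code{GRanges} (with \code{name}/\code{score} columns and strand
#'   when 6 columns are present).
#' @export
readBed <- function(path, chromSizes = NULL) {
  pb <- .parseBedLines(path, 3L)
  parts <- pb$parts
  chrom <- vapply(parts, `[`, character(1), 1)
  start0 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  end0 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 3)))
  if (anyNA(start0) || anyNA(end0)) {
    .ioStop(path, pb$lineNo[which(is.na(start0) | is.na(end0))[1]],
            "coordinates are not numbers")
  }
  bad <- start0 >= end0 | start0 < 0
  if (any(bad)) {
    .ioStop(path, pb$lineNo[which(bad)[1]],
            "invalid interval (need 0 <= start < end)")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1, end0))
  ncols <- vapply(parts, length, integer(1))
  if (all(ncols >= 6)) {
    gr$name <- vapply(parts, `[`, character(1), 4)
    gr$score <- suppressWarnings(
      as.numeric(vapply(parts, `[`, character(1), 5)))
    st <- vapply(parts, `[`, character(1), 6)
    st[!st %in% c("+", "-")] <- "*"
    GenomicRanges::strand(gr) <- st
  }
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlengths(gr) <-
      chromSizes[GenomeInfoDb::seqlevels(gr)]
  }
  gr
}

#' Write GRanges as BED
#'
#' @param gr \code{GRanges}; with \code{ncols = 6}, name/score/strand are
#'   written (defaults \code{"."}, 0, \code{"."}).
#' @param path output file.
#' @param ncols 3 or 6.
#' @return The path, invisibly.
#' @export
writeBed <- function(gr, path, ncols = 3L) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  if (ncols >= 6) {
    name <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
    score <- if (!is.null(gr$score)) gr$score else rep(0, length(gr))
    st <- as.character(GenomicRanges::strand(gr))
    st[st == "*"] <- "."
    out <- paste(chrom, start0, end0, name, score, st, sep = "\t")
  } else {
    out <- paste(chrom, start0, end0, sep = "\t")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write gene models as BED12
#'
#' Single-block records spanning the gene; thickStart/thickEnd cover the
#' whole span.
#'
#' @param genes \code{GRanges} with \code{name} (and optional exon
#'   structure, ignored: one block per gene).
#' @param path output file.
#' @export
writeGenesBed12 <- function(genes, path) {
  chrom <- as.character(GenomicRanges::seqnames(genes))
  start0 <- GenomicRanges::start(genes) - 1L
  end0 <- GenomicRanges::end(genes)
  name <- if (!is.null(genes$name)) genes$name else
    paste0("gene", seq_along(genes))
  st <- as.character(GenomicRanges::strand(genes))
  st[st == "*"] <- "."
  size <- end0 - start0
  out <- paste(chrom, start0, end0, name, 0, st, start0, end0, "0,0,0",
               1, paste0(size, ","), "0,", sep = "\t")
  writeLines(out, path)
  invisible(path)
}

#' Read BED12 gene models
#'
#' @param path BED12 file.
#' @param chromSizes optional named lengths.
#' @return \code{GRanges} with \code{name} and a \code{tss} column derived
#'   from the strand.
#' @export
readGenesBed12 <- function(path, chromSizes = NULL) {
  gr <- readBed(path, chromSizes)
  st <- as.character(GenomicRanges::strand(gr))
  gr$tss <- ifelse(st == "-", GenomicRanges::end(gr),
                   GenomicRanges::start(gr))
  gr
}

#' Read and write bedGraph tracks
#'
#' The canonical writer emits maximal runs of equal non-zero value
#' (0-based half-open); the reader fills unlisted bases with zero, so
#' write--read round trips preserve every value and read--write round
#' trips on canonical files are byte-identical.
#'
#' @param path bedGraph file.
#' @param chromSizes named chromosome lengths (required to size the
#'   track).
#' @return \code{readBedGraph}: a \linkS4class{GenomeTrack}.
#' @export
readBedGraph <- function(path, chromSizes) {
  values <- lapply(chromSizes, function(L) numeric(L))
  pb <- .parseBedLines(path, 4L)
  parts <- pb$parts
  chrom <- vapply(parts, `[`, character(1), 1)
  unknown <- !(chrom %in% names(chromSizes))
  if (any(unknown)) {
    .ioStop(path, pb$lineNo[which(unknown)[1]],
            paste("unknown chromosome", chrom[which(unknown)[1]]))
  }
  start0 <- as.numeric(vapply(parts, `[`, character(1), 2))
  end0 <- as.numeric(vapply(parts, `[`, character(1), 3))
  val <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 4)))
  if (anyNA(val)) {
    .ioStop(path, pb$lineNo[which(is.na(val))[1]], "value is not a number")
  }
  bad <- start0 >= end0 | start0 < 0 | end0 > chromSizes[chrom]
  if (any(bad)) {
    .ioStop(path, pb$lineNo[which(bad)[1]], "interval out of bounds")
  }
  for (i in seq_along(chrom)) {
    values[[chrom[i]]][(start0[i] + 1):end0[i]] <- val[i]
  }
  GenomeTrack(values)
}

#' @rdname readBedGraph
#' @param track a \linkS4class{GenomeTrack}.
#' @param digits significant digits for values (default 6).
#' @export
writeBedGraph <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track@values)) {
    v <- track@values[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    nz <- r$values != 0
    if (!any(nz)) next
    writeLines(paste(chrom, starts[nz] - 1L, ends[nz],
                     format(signif(r$values[nz], digits), trim = TRUE,
                            scientific = FALSE),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Write a track as fixedStep wiggle
#'
#' One declaration line per chromosome (\code{start=1 step=1}), one value
#' per line (1-based per the wiggle specification).
#'
#' @param track a \linkS4class{GenomeTrack}.
#' @param path output file.
#' @param digits significant digits (default 6).
#' @export
writeWiggle <- function(track, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track@values)) {
    writeLines(sprintf("fixedStep chrom=%s start=1 step=1", chrom), con)
    writeLines(format(signif(track@values[[chrom]], digits), trim = TRUE,
                      scientific = FALSE), con)
  }
  invisible(path)
}

#' Read a fixedStep wiggle track
#'
#' @param path wiggle file (fixedStep, step=1 declarations).
#' @param chromSizes optional named lengths; chromosomes absent from the
#'   file are zero-filled.
#' @return A \linkS4class{GenomeTrack}.
#' @export
readWiggle <- function(path, chromSizes = NULL) {
  lines <- readLines(path)
  decl <- grep("^fixedStep", lines)
  if (!length(decl)) .ioStop(path, 1, "no fixedStep declaration found")
  values <- if (is.null(chromSizes)) list() else
    lapply(chromSizes, function(L) numeric(L))
  bounds <- c(decl, length(lines) + 1L)
  for (i in seq_along(decl)) {
    hdr <- lines[decl[i]]
    chrom <- sub('.*chrom=([^ ]+).*', '\\1', hdr)
    start <- as.integer(sub('.*start=([0-9]+).*', '\\1', hdr))
    body <- lines[(decl[i] + 1L):(bounds[i + 1L] - 1L)]
    v <- suppressWarnings(as.numeric(body))
    if (anyNA(v)) {
      .ioStop(path, decl[i] + which(is.na(v))[1], "value is not a number")
    }
    L <- if (!is.null(chromSizes)) chromSizes[[chrom]] else
      start + length(v) - 1L
    if (is.null(values[[chrom]])) values[[chrom]] <- numeric(L)
    values[[chrom]][start:(start + length(v) - 1L)] <- v
  }
  GenomeTrack(values)
}

#' Read and write methylation site tables
#'
#' Three tab-separated columns: chrom, 0-based position, context (one of
#' mCG, mCHG, mCHH, hmC).  On ingest, mCG records at positions that also
#' carry an hmC record are removed (methylcytosine calls later shown to be
#' hydroxymethylated are not counted as mCG).
#'
#' @param path TSV file.
#' @param chromSizes optional named lengths.
#' @return \code{readMethylationTsv}: sorted \code{GRanges} with a
#'   \code{context} column.
#' @export
readMethylationTsv <- function(path, chromSizes = NULL) {
  pb <- .parseBedLines(path, 3L)
  parts <- pb$parts
  chrom <- vapply(parts, `[`, character(1), 1)
  pos0 <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2)))
  ctx <- vapply(parts, `[`, character(1), 3)
  if (anyNA(pos0)) {
    .ioStop(path, pb$lineNo[which(is.na(pos0))[1]],
            "position is not a number")
  }
  badCtx <- !ctx %in% CONTEXTS
  if (any(badCtx)) {
    .ioStop(path, pb$lineNo[which(badCtx)[1]],
            paste("unknown context", ctx[which(badCtx)[1]]))
  }
  key <- paste(chrom, pos0)
  hmcKey <- key[ctx == "hmC"]
  drop <- ctx == "mCG" & key %in% hmcKey
  chrom <- chrom[!drop]; pos0 <- pos0[!drop]; ctx <- ctx[!drop]
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1, width = 1L),
                               context = ctx)
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlengths(gr) <- chromSizes[GenomeInfoDb::seqlevels(gr)]
  }
  sort(gr)
}

#' @rdname readMethylationTsv
#' @param sites \code{GRanges} with a \code{context} column.
#' @export
writeMethylationTsv <- function(sites, path) {
  writeLines(paste(as.character(GenomicRanges::seqnames(sites)),
                   GenomicRanges::start(sites) - 1L,
                   sites$context, sep = "\t"), path)
  invisible(path)
}

#' Write called nucleosomes as BED6+2
#'
#' Columns: chrom, core start/end (0-based half-open), name
#' (\code{nuc<i>}), score (rounded summit NOS), strand \code{"."}, then
#' the 0-based dyad and the core-mean NOS.
#'
#' @param nucleosomes \code{GRanges} from \code{\link{callNucleosomes}}.
#' @param path output file.
#' @export
writeNucleosomesBed <- function(nucleosomes, path) {
  nm <- names(nucleosomes)
  if (is.null(nm)) nm <- sprintf("nuc%d", seq_along(nucleosomes))
  writeLines(paste(
    as.character(GenomicRanges::seqnames(nucleosomes)),
    GenomicRanges::start(nucleosomes) - 1L,
    GenomicRanges::end(nucleosomes),
    nm, round(nucleosomes$summitNos), ".",
    nucleosomes$dyad - 1L,
    format(signif(nucleosomes$meanNos, 6), trim = TRUE,
           scientific = FALSE),
    sep = "\t"), path)
  invisible(path)
}

#' Read a BED6+2 nucleosome file
#'
#' @param path file written by \code{\link{writeNucleosomesBed}}.
#' @param chromSizes optional named lengths.
#' @return \code{GRanges} with \code{dyad}, \code{summitNos} (the score
#'   column) and \code{meanNos}.
#' @export
readNucleosomesBed <- function(path, chromSizes = NULL) {
  pb <- .parseBedLines(path, 8L)
  parts <- pb$parts
  gr <- readBed(path, chromSizes)
  gr$summitNos <- gr$score
  gr$dyad <- as.integer(vapply(parts, `[`, character(1), 7)) + 1L
  gr$meanNos <- as.numeric(vapply(parts, `[`, character(1), 8))
  gr
}

#' Write a genome as FASTA (60-column wrap)
#'
#' @param genome named \code{DNAStringSet}.
#' @param path output file.
#' @export
writeGenomeFasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
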