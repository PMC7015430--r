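#' Parse a SAM file into footprint alignments
#'
#' Reads a text SAM file (with \code{@SQ} headers) and extracts, per primary
#' mapped record: the aligned genomic blocks (CIGAR \code{M/=/X/D} consume
#' and cover the reference; \code{N} splits blocks; \code{S} and \code{I}
#' consume query only), strand from flag bit 0x10, MAPQ, the aligned query
#' length, and optionally a UMI taken from the read-name suffix after the
#' last underscore.
#'
#' Unmapped (0x4), secondary (0x100) and supplementary (0x800) records are
#' excluded unless \code{keepAll = TRUE}. Records whose sequence length
#' disagrees with the CIGAR query length are skipped and counted in a
#' warning.
#'
#' @param path SAM file path.
#' @param umi logical; parse UMIs from read names.
#' @param keepAll logical; retain unmapped/secondary/supplementary records.
#' @param mapqThreshold exclude records with MAPQ below this (default 0,
#'   keep all primaries; multimap policy is the aligner's business).
#' @return A \linkS4class{FootprintAlignments}.
#' @export
parseSAM <- function(path, umi = FALSE, keepAll = FALSE, mapqThreshold = 0L) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (!length(body)) return(emptyAlignments())
  parts <- strsplit(body, "\t", fixed = TRUE)
  flag <- as.integer(vapply(parts, `[`, "", 2L))
  cigar <- vapply(parts, `[`, "", 6L)
  seq <- vapply(parts, `[`, "", 10L)
  keep <- rep(TRUE, length(parts))
  if (!keepAll)
    keep <- bitwAnd(flag, 0x4L + 0x100L + 0x800L) == 0L
  # CIGAR/SEQ consistency: SEQ length must equal full query length
  qlenFull <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  bad <- keep & seq != "*" & nchar(seq) != qlenFull
  if (any(bad)) {
    warning(sum(bad), " record(s) skipped: CIGAR/sequence length mismatch")
    keep <- keep & !bad
  }
  if (mapqThreshold > 0L) {
    mapqAll <- as.integer(vapply(parts, `[`, "", 5L))
    keep <- keep & mapqAll >= mapqThreshold
  }
  parts <- parts[keep]
  if (!length(parts)) return(emptyAlignments())
  flag <- flag[keep]
  cigar <- cigar[keep]
  qname <- vapply(parts, `[`, "", 1L)
  chrom <- vapply(parts, `[`, "", 3L)
  pos <- as.integer(vapply(parts, `[`, "", 4L))
  mapq <- as.integer(vapply(parts, `[`, "", 5L))
  strand <- ifelse(bitwAnd(flag, 0x10L) > 0L, "-", "+")
  readLength <- GenomicAlignments::cigarWidthAlongQuerySpace(
    cigar, after.soft.clipping = TRUE)
  blockList <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = c("M", "=", "X", "D"), reduce.ranges = TRUE)
  nb <- lengths(blockList)
  flat <- unlist(blockList, use.names = FALSE)
  blocks <- GRanges(rep(chrom, nb), flat, strand = rep(strand, nb))
  mcols(blocks)$readIdx <- rep(seq_along(parts), nb)
  pos5 <- ifelse(strand == "+",
                 vapply(seq_along(blockList),
                        function(i) min(start(blockList[[i]])), 1L),
                 vapply(seq_along(blockList),
                        function(i) max(end(blockList[[i]])), 1L))
  reads <- data.frame(
    readId = qname, chrom = chrom, strand = strand,
    pos5 = as.integer(pos5), readLength = readLength, mapq = mapq,
    flag = flag,
    umi = if (umi) sub(".*_", "", qname) else NA_character_,
    duplicate = NA, stringsAsFactors = FALSE)
  new("FootprintAlignments", reads = reads, blocks = blocks)
}

emptyAlignments <- function() {
  new("FootprintAlignments",
      reads = data.frame(readId = character(), chrom = character(),
                         strand = character(), pos5 = integer(),
                         readLength = integer(), mapq = integer(),
                         flag = integer(), umi = character(),
                         duplicate = logical(), stringsAsFactors = FALSE),
      blocks = GRanges())
}

#' @rdname FootprintAlignments-class
#' @param x a \linkS4class{FootprintAlignments}.
#' @export
nReads <- function(x) nrow(x@reads)

#' @rdname FootprintAlignments-class
#' @export
readTable <- function(x) x@reads

#' @rdname FootprintAlignments-class
#' @export
alignedBlocks <- function(x) x@blocks

#' Subset alignments by read index
#' @param x a \linkS4class{FootprintAlignments}.
#' @param i integer or logical index over reads.
#' @export
subsetReads <- function(x, i) {
  idx <- seq_len(nReads(x))[i]
  keepBlock <- mcols(x@blocks)$readIdx %in% idx
  blocks <- x@blocks[keepBlock]
  mcols(blocks)$readIdx <- match(mcols(blocks)$readIdx[seq_len(sum(keepBlock))],
                                 idx)
  new("FootprintAlignments", reads = x@reads[idx, , drop = FALSE],
      blocks = blocks)
}

setMethod("show", "FootprintAlignments", function(object) {
  cat("FootprintAlignments:", nReads(object), "reads,",
      length(object@blocks), "aligned blocks\n")
})

#' Per-base genomic coverage over an interval
#'
#' \code{counts[p]} is the number of aligned blocks covering genomic
#' position p; spliced reads contribute nothing across their N gaps.
#'
#' @param alignments \linkS4class{FootprintAlignments}.
#' @param chrom chromosome id.
#' @param start,end 1-based closed interval bounds (end >= start).
#' @return A \linkS4class{CoverageTrack} in genomic space.
#' @export
genomicCoverage <- function(alignments, chrom, start, end) {
  if (end < start) stop("empty interval: end < start")
  b <- alignments@blocks
  b <- b[as.character(seqnames(b)) == chrom]
  cov <- coverage(IRanges::ranges(b), width = max(end, max(c(0L, end(b)))))
  counts <- as.integer(cov[start:end])
  new("CoverageTrack", space = "genomic", ref = chrom,
      offset = as.integer(start), counts = counts)
}

#' @rdname CoverageTrack-class
#' @param x a \linkS4class{CoverageTrack}.
#' @export
trackCounts <- function(x) x@counts

setMethod("show", "CoverageTrack", function(object) {
  cat(sprintf("CoverageTrack (%s) %s: %d positions, total %d\n",
              object@space, object@ref, length(object@counts),
              sum(object@counts)))
})
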