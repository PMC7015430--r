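#' Build the intron-collapsed coordinate map of a transcript
#'
#' Bijection between the transcript's exonic genomic positions and exon-space
#' positions 1..L (L = exonic length). Exon-space position 1 is the
#' transcript's 5' end: the lowest genomic exonic coordinate on \code{+},
#' the highest on \code{-}.
#'
#' @param model \linkS4class{TranscriptModel} with at least one exon.
#' @return An \linkS4class{ExonCoordinateMap}.
#' @export
buildExonMap <- function(model) {
  if (!length(model@exons)) stop("transcript has no exons")
  g <- unlist(lapply(seq_along(model@exons), function(i)
    start(model@exons)[i]:end(model@exons)[i]))
  L <- length(g)
  e <- if (model@strand == "+") seq_len(L) else rev(seq_len(L))
  new("ExonCoordinateMap", transcriptId = model@transcriptId,
      genomicPos = as.integer(g), exonicPos = as.integer(e))
}

#' @rdname ExonCoordinateMap-class
#' @param map an \linkS4class{ExonCoordinateMap}.
#' @param pos genomic positions.
#' @return exon-space positions (NA for non-exonic input).
#' @export
genomicToExonic <- function(map, pos) {
  map@exonicPos[match(pos, map@genomicPos)]
}

#' @rdname ExonCoordinateMap-class
#' @param i exon-space positions 1..L.
#' @export
exonicToGenomic <- function(map, i) {
  map@genomicPos[match(i, map@exonicPos)]
}

#' @rdname ExonCoordinateMap-class
#' @export
exonicSpan <- function(map) length(map@genomicPos)

# genomic intervals (ascending IRanges) of exon-space range [from, to]
exonicRangeToGenomic <- function(map, from, to) {
  g <- sort(exonicToGenomic(map, from:to))
  IRanges::reduce(IRanges(g, g))
}

# exon-space position of the CDS start / end (transcript orientation)
cdsExonicBounds <- function(model, map = buildExonMap(model)) {
  if (!length(model@cds)) return(c(NA_integer_, NA_integer_))
  e <- genomicToExonic(map, unlist(lapply(seq_along(model@cds), function(i)
    start(model@cds)[i]:end(model@cds)[i])))
  c(min(e), max(e))
}

#' Intron-collapsed coverage profile of one gene
#'
#' Per-base aligned-block coverage projected into exon space, with the CDS
#' and UTR boundaries reported in exon-space coordinates so initiation/
#' termination context and uORF signal are visible without intron gaps.
#'
#' @param alignments \linkS4class{FootprintAlignments}.
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @param gene gene id (its first transcript is profiled) or a transcript id.
#' @return list: \code{track} (\linkS4class{CoverageTrack}, exonic space),
#'   \code{cdsStart}, \code{cdsEnd} (exon-space, NA if no CDS),
#'   \code{transcriptId}.
#' @export
geneCoverage <- function(alignments, annotation, gene) {
  tid <- if (gene %in% names(annotation@transcripts)) gene
         else if (gene %in% names(annotation@genes)) annotation@genes[[gene]][1L]
         else stop("gene or transcript not in annotation: ", gene)
  model <- annotation@transcripts[[tid]]
  map <- buildExonMap(model)
  b <- alignments@blocks
  b <- b[as.character(seqnames(b)) == model@chrom]
  L <- exonicSpan(map)
  counts <- integer(L)
  if (length(b)) {
    span <- max(c(end(b), max(map@genomicPos)))
    cov <- coverage(IRanges::ranges(b), width = span)
    counts <- as.integer(cov[map@genomicPos])[order(map@exonicPos)]
  }
  bounds <- cdsExonicBounds(model, map)
  list(track = new("CoverageTrack", space = "exonic", ref = tid,
                   offset = 1L, counts = counts),
       cdsStart = bounds[1L], cdsEnd = bounds[2L], transcriptId = tid)
}

# strand-aware 5'-most exonic position of each read on a transcript;
# NA for reads with no exonic base. Reads are attributed when >= 1 aligned
# base overlaps the exons.
readFivePrimeExonic <- function(alignments, model, map = buildExonMap(model)) {
  b <- alignments@blocks
  onChrom <- as.character(seqnames(b)) == model@chrom
  b <- b[onChrom]
  hits <- IRanges::findOverlaps(IRanges::ranges(b), model@exons)
  out <- rep(NA_integer_, nReads(alignments))
  if (!length(hits)) return(out)
  qh <- S4Vectors::queryHits(hits)
  ov <- IRanges::pintersect(IRanges::ranges(b)[qh],
                            model@exons[S4Vectors::subjectHits(hits)])
  readIdx <- mcols(b)$readIdx[qh]
  # min exon-space position per read among overlapped bases: for each
  # overlap interval, candidate extremes are its two ends mapped to exon
  # space (the map is monotone within an exon).
  e1 <- genomicToExonic(map, start(ov))
  e2 <- genomicToExonic(map, end(ov))
  cand <- pmin(e1, e2)
  agg <- tapply(cand, readIdx, min)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Metagene profile across transcripts
#'
#' Each read contributes one unit at its 5'-most exon-space position on each
#' transcript it overlaps. Per transcript, the positional counts over the
#' transcript (or its CDS, with \code{cdsOnly}) are binned into \code{bins}
#' equal-width meta-bins, divided by the transcript's total (making every
#' transcript's contribution sum to 1), and averaged with equal weight
#' across transcripts with total coverage >= \code{minCoverage}. Per-
#' transcript normalization makes the profile invariant to expression
#' level, so super-expressors cannot dominate.
#'
#' @param alignments \linkS4class{FootprintAlignments}.
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @param bins number of meta-bins (default 100).
#' @param cdsOnly restrict to CDS exon-space (transcripts without CDS are
#'   skipped).
#' @param minCoverage minimum reads on a transcript for inclusion
#'   (default 10).
#' @param label sample label carried on the result.
#' @return A \linkS4class{MetageneProfile}.
#' @export
metagene <- function(alignments, annotation, bins = 100L, cdsOnly = FALSE,
                     minCoverage = 10L, label = "sample") {
  bins <- as.integer(bins)
  acc <- numeric(bins)
  n <- 0L
  nExcluded <- 0L
  for (tid in names(annotation@transcripts)) {
    model <- annotation@transcripts[[tid]]
    if (!length(model@exons)) next
    map <- buildExonMap(model)
    p <- readFivePrimeExonic(alignments, model, map)
    p <- p[!is.na(p)]
    L <- exonicSpan(map)
    if (cdsOnly) {
      bounds <- cdsExonicBounds(model, map)
      if (is.na(bounds[1L])) next
      p <- p[p >= bounds[1L] & p <= bounds[2L]] - bounds[1L] + 1L
      L <- bounds[2L] - bounds[1L] + 1L
    }
    tot <- length(p)
    if (tot < minCoverage) {
      nExcluded <- nExcluded + 1L
      next
    }
    b <- pmin(floor(bins * (p - 1L) / L) + 1L, bins)
    acc <- acc + tabulate(b, nbins = bins) / tot
    n <- n + 1L
  }
  if (n == 0L) {
    warning("no transcript passed the coverage threshold; empty profile")
    return(new("MetageneProfile", bins = numeric(bins), nTranscripts = 0L,
               nExcluded = nExcluded, label = label))
  }
  new("MetageneProfile", bins = acc / n, nTranscripts = n,
      nExcluded = nExcluded, label = label)
}

#' @rdname MetageneProfile-class
#' @param x a \linkS4class{MetageneProfile}.
#' @export
profileBins <- function(x) x@bins

setMethod("show", "MetageneProfile", function(object) {
  cat(sprintf("MetageneProfile '%s': %d bins, %d transcripts (%d excluded)\n",
              object@label, length(object@bins), object@nTranscripts,
              object@nExcluded))
})

#' Codon phasing / P-site periodicity profile
#'
#' For each footprint, the 5' end is located in each overlapping
#' transcript's exon space and its distance to the annotated start codon is
#' taken. In \code{auto} mode the P-site offset per read length is the modal
#' distance from 5' ends to start codons, computed over reads whose 5' end
#' falls within -50..0 of a start; the P-site is then 5' end + offset in
#' transcript orientation. Frames are (P-site - CDS start) mod 3 in coding
#' space, for P-sites inside the CDS; the start-relative histogram spans
#' -50..+150.
#'
#' @param alignments \linkS4class{FootprintAlignments}.
#' @param annotation \linkS4class{GenomeAnnotation} with CDS records.
#' @param offsetMode \code{"auto"} (modal, per read length) or
#'   \code{"fixed"}.
#' @param fixedOffset offset used in fixed mode, and the fallback (with a
#'   warning) when auto mode finds no start-proximal reads; default 16.
#' @return A \linkS4class{PhasingProfile}.
#' @export
phasing <- function(alignments, annotation, offsetMode = c("auto", "fixed"),
                    fixedOffset = 16L) {
  offsetMode <- match.arg(offsetMode)
  dists <- integer(0)    # 5' end position relative to start codon
  lens <- integer(0)
  cdsLens <- integer(0)  # coding length of the transcript for each entry
  for (tid in names(annotation@transcripts)) {
    model <- annotation@transcripts[[tid]]
    if (!length(model@cds) || !length(model@exons)) next
    map <- buildExonMap(model)
    bounds <- cdsExonicBounds(model, map)
    p <- readFivePrimeExonic(alignments, model, map)
    ok <- !is.na(p)
    if (!any(ok)) next
    dists <- c(dists, p[ok] - bounds[1L])
    lens <- c(lens, alignments@reads$readLength[ok])
    cdsLens <- c(cdsLens, rep(bounds[2L] - bounds[1L] + 1L, sum(ok)))
  }
  if (offsetMode == "auto") {
    nearStart <- dists >= -50L & dists <= 0L
    if (!any(nearStart)) {
      warning("no reads near annotated starts; falling back to fixed offset ",
              fixedOffset)
      offsets <- structure(integer(0))
      offsetMode <- "fixed"
    } else {
      globalOffset <- modalValue(-dists[nearStart])
      # lengths too rare near starts inherit the global modal offset
      perLen <- split(-dists[nearStart], lens[nearStart])
      offsets <- vapply(perLen, function(d)
        if (length(d) >= 30L) modalValue(d) else globalOffset, integer(1))
    }
  }
  if (offsetMode == "fixed") {
    offsets <- integer(0)
    globalOffset <- as.integer(fixedOffset)
  }
  off <- offsets[as.character(lens)]
  off[is.na(off)] <- globalOffset
  psite <- dists + off
  inHist <- psite >= -50L & psite <= 150L
  hist <- tabulate(psite[inHist] + 51L, nbins = 201L)
  names(hist) <- as.character(-50:150)
  inCds <- psite >= 0L & psite < cdsLens
  frames <- tabulate((psite[inCds] %% 3L) + 1L, nbins = 3L)
  names(frames) <- c("0", "1", "2")
  new("PhasingProfile", frameCounts = as.integer(frames),
      startHistogram = as.integer(hist),
      offsets = if (length(offsets)) offsets else
        structure(as.integer(fixedOffset), names = "all"),
      offsetMode = offsetMode)
}

modalValue <- function(x) {
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' @rdname PhasingProfile-class
#' @param x a \linkS4class{PhasingProfile}.
#' @export
frameCounts <- function(x) {
  structure(x@frameCounts, names = c("0", "1", "2"))
}

#' @rdname PhasingProfile-class
#' @export
startHistogram <- function(x) {
  structure(x@startHistogram, names = as.character(-50:150))
}

#' @rdname PhasingProfile-class
#' @export
psiteOffsets <- function(x) x@offsets

setMethod("show", "PhasingProfile", function(object) {
  fc <- frameCounts(object)
  cat(sprintf("PhasingProfile (%s offsets): frames 0/1/2 = %d/%d/%d\n",
              object@offsetMode, fc[1L], fc[2L], fc[3L]))
})
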