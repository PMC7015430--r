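# Shared fixture builders and independent oracles.

makeModel <- function(exons, cds = IRanges::IRanges(), strand = "+",
                      tid = "tx1", gid = "g1", biotype = "protein_coding",
                      canonical = FALSE) {
  methods::new("TranscriptModel", transcriptId = tid, geneId = gid,
               chrom = "chr1", strand = strand, biotype = biotype,
               exons = exons, cds = cds, canonical = canonical,
               flags = character())
}

ir <- function(starts, ends) IRanges::IRanges(starts, ends)

# base-by-base truncation oracle: enumerate coding positions in transcript
# orientation, drop the first trim5 and last trim3, reassemble intervals
bruteTruncate <- function(cds, strand, trim5, trim3, minRemaining = 3L) {
  pos <- sort(unlist(Map(seq, IRanges::start(cds), IRanges::end(cds))))
  if (strand == "-") pos <- rev(pos)
  if (length(pos) <= trim5 + trim3 + minRemaining) return(cds)
  keep <- sort(pos[(trim5 + 1L):(length(pos) - trim3)])
  IRanges::reduce(IRanges::IRanges(keep, keep))
}

# random multi-segment CDS model (exons coincide with CDS segments)
randomCdsModel <- function(strand = sample(c("+", "-"), 1L)) {
  k <- sample(1:5, 1L)
  widths <- sample(5:120, k, replace = TRUE)
  gaps <- sample(30:200, k, replace = TRUE)
  starts <- cumsum(c(100L, head(widths + gaps, -1L)))
  cds <- IRanges::IRanges(starts, width = widths)
  makeModel(cds, cds, strand = strand)
}

# write a minimal SAM file from a record table
writeSam <- function(path, reads, chromLen = 100000L, chrom = "chr1") {
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             paste0("@SQ\tSN:", chrom, "\tLN:", chromLen))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    seqlen <- GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar)
    lines <- c(lines, sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                              r$qname, r$flag, chrom, r$pos,
                              if (is.null(r$mapq)) 255L else r$mapq, r$cigar,
                              if (!is.null(r$seq) && !is.na(r$seq)) r$seq
                              else strrep("A", seqlen),
                              strrep("I", seqlen)))
  }
  writeLines(lines, path)
  path
}

samRead <- function(qname, pos, cigar, flag = 0L, mapq = 255L, seq = NULL) {
  data.frame(qname = qname, pos = pos, cigar = cigar, flag = flag,
             mapq = mapq, seq = if (is.null(seq)) NA_character_ else seq,
             stringsAsFactors = FALSE)
}

writeFastq <- function(path, seqs) {
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+",
                             strrep("I", nchar(seqs)))), path)
  path
}

# per-base brute-force intersection-nonempty oracle over a feature table
# (data.frame: gene_id, start, end); blocks is a list of 2-col matrices
bruteAssign <- function(blockList, featTable) {
  vapply(blockList, function(bl) {
    basePos <- unlist(lapply(seq_len(nrow(bl)), function(i)
      bl[i, 1L]:bl[i, 2L]))
    sets <- lapply(basePos, function(p)
      unique(featTable$gene_id[featTable$start <= p & featTable$end >= p]))
    sets <- sets[lengths(sets) > 0L]
    if (!length(sets)) return("__no_feature")
    inter <- Reduce(intersect, sets)
    if (length(inter) == 1L) inter else "__ambiguous"
  }, "")
}

# O(n^2) substring transitive-closure oracle: repeatedly merge any pair
# where one sequence contains the other, until stable
bruteMergeGroups <- function(seqs) {
  groups <- as.list(seq_along(seqs))
  repeat {
    merged <- FALSE
    for (a in seq_along(groups)) {
      if (merged) break
      for (b in seq_along(groups)) {
        if (a >= b) next
        pairHit <- any(outer(groups[[a]], groups[[b]], Vectorize(function(i, j)
          grepl(seqs[i], seqs[j], fixed = TRUE) ||
            grepl(seqs[j], seqs[i], fixed = TRUE))))
        if (pairHit) {
          groups[[a]] <- c(groups[[a]], groups[[b]])
          groups[[b]] <- NULL
          merged <- TRUE
          break
        }
      }
    }
    if (!merged) break
  }
  lapply(groups, function(idx) sort(seqs[idx]))
}

# tiny hand-written GTF with explicit biotypes/tags
writeTinyGtf <- function(path, lines) {
  writeLines(lines, path)
  path
}

gtfLine <- function(feature, start, end, strand = "+", attrs, frame = ".") {
  paste("chr1", "test", feature, start, end, ".", strand, frame, attrs,
        sep = "\t")
}

# two genes with CDS [101,200] (gA) and [181,280] (gB): overlap 181..200
twoGeneGtf <- function() {
  aA <- 'gene_id "gA"; transcript_id "tA"; gene_biotype "protein_coding";'
  aB <- 'gene_id "gB"; transcript_id "tB"; gene_biotype "protein_coding";'
  path <- withr::local_tempfile(fileext = ".gtf", .local_envir = parent.frame())
  writeTinyGtf(path, c(
    gtfLine("gene", 101, 200, attrs = 'gene_id "gA";'),
    gtfLine("transcript", 101, 200, attrs = aA),
    gtfLine("exon", 101, 200, attrs = aA),
    gtfLine("CDS", 101, 200, attrs = aA, frame = "0"),
    gtfLine("gene", 181, 280, attrs = 'gene_id "gB";'),
    gtfLine("transcript", 181, 280, attrs = aB),
    gtfLine("exon", 181, 280, attrs = aB),
    gtfLine("CDS", 181, 280, attrs = aB, frame = "0")))
  path
}
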