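#' Mark PCR duplicates
#'
#' Reads sharing (chromosome, strand, strand-aware 5'-most aligned
#' position, aligned length) — plus the UMI when \code{useUmi} — form a
#' duplicate group. One representative per group (highest MAPQ, ties by
#' smallest read id) stays unflagged; the rest are flagged. Keying on 5'
#' position plus aligned length rather than the full block structure is
#' robust for footprint-length reads.
#'
#' @param alignments \linkS4class{FootprintAlignments}.
#' @param useUmi include the UMI in the duplicate key (UMIs separate
#'   biological from PCR duplicates, so flagged counts can only shrink).
#' @return The alignments with the \code{duplicate} column filled.
#' @export
markDuplicates <- function(alignments, useUmi = FALSE) {
  r <- alignments@reads
  if (!nrow(r)) return(alignments)
  key <- paste(r$chrom, r$strand, r$pos5, r$readLength,
               if (useUmi) r$umi else "", sep = "\r")
  dup <- logical(nrow(r))
  for (idx in split(seq_len(nrow(r)), key)) {
    if (length(idx) == 1L) next
    rep <- idx[order(-r$mapq[idx], r$readId[idx])][1L]
    dup[setdiff(idx, rep)] <- TRUE
  }
  alignments@reads$duplicate <- dup
  alignments
}

#' Per-gene duplication rate versus expression
#'
#' Assigns reads to genes with intersection-nonempty semantics, then
#' reports, per gene with at least one read: total reads, unique
#' (non-duplicate) reads, duplication rate 1 - unique/total, and expression
#' as reads per kilobase of feature length. The scatter of duplication rate
#' against expression is the library-complexity diagnostic: well-behaved
#' libraries show low rates except at extreme expression.
#'
#' @param alignments duplicate-marked \linkS4class{FootprintAlignments}
#'   (run \code{\link{markDuplicates}} first).
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @param featureType feature to assign reads over (default \code{"exon"}).
#' @return data.frame: gene, reads_total, reads_unique, duplication_rate,
#'   expression; attribute \code{"zero_read_genes"} counts excluded genes.
#' @export
complexityProfile <- function(alignments, annotation, featureType = "exon") {
  if (!length(annotation@genes)) stop("empty annotation")
  if (all(is.na(alignments@reads$duplicate)))
    stop("duplicates not marked; run markDuplicates() first")
  res <- countReads(alignments, annotation, featureType = featureType)
  gene <- unname(res$assignments)
  dup <- alignments@reads$duplicate
  ok <- !is.na(gene)
  tot <- table(gene[ok])
  uni <- table(gene[ok & !dup])
  lens <- geneFeatureLengths(annotation, featureType)
  genes <- names(tot)
  out <- data.frame(
    gene = genes,
    reads_total = as.integer(tot),
    reads_unique = as.integer(uni[genes]),
    stringsAsFactors = FALSE)
  out$reads_unique[is.na(out$reads_unique)] <- 0L
  out$duplication_rate <- 1 - out$reads_unique / out$reads_total
  out$expression <- out$reads_total / (lens[genes] / 1e3)
  attr(out, "zero_read_genes") <- sum(!names(annotation@genes) %in% genes)
  rownames(out) <- NULL
  out
}
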