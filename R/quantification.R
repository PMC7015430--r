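#' Per-gene feature intervals
#'
#' Collapses all records of one feature type to per-gene reduced interval
#' sets (union across isoforms, so a read on any isoform of a gene is that
#' gene's read).
#'
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @param featureType one of the feature values present in the GTF, e.g.
#'   \code{"CDS"}, \code{"exon"}, \code{"five_prime_utr"},
#'   \code{"three_prime_utr"}.
#' @return \linkS4class{GRanges} with mcol \code{gene_id}.
#' @export
geneFeatures <- function(annotation, featureType = "CDS") {
  rec <- annotation@records
  sel <- rec$feature == featureType
  if (!any(sel))
    stop("no records of feature type '", featureType, "'; available: ",
         paste(sort(unique(rec$feature)), collapse = ", "))
  rec <- rec[sel, , drop = FALSE]
  gr <- GRanges(rec$seqname, IRanges(rec$start, rec$end),
                strand = ifelse(rec$strand %in% c("+", "-"), rec$strand, "*"))
  mcols(gr)$gene_id <- rec$gene_id
  grl <- S4Vectors::split(gr, mcols(gr)$gene_id)
  red <- unlist(GenomicRanges::reduce(grl))
  mcols(red)$gene_id <- names(red)
  names(red) <- NULL
  red
}

# coordinate equality of two reduced interval sets
sameRanges <- function(a, b) {
  length(a) == length(b) && all(start(a) == start(b)) &&
    all(end(a) == end(b))
}

#' Union feature length per gene
#'
#' Per-gene length (nt) of the reduced union of \code{featureType}
#' intervals across isoforms, in annotation gene order; genes without the
#' feature get length 0.
#'
#' @inheritParams geneFeatures
#' @return Named integer vector.
#' @export
geneFeatureLengths <- function(annotation, featureType = "CDS") {
  feats <- geneFeatures(annotation, featureType)
  w <- tapply(width(feats), mcols(feats)$gene_id, sum)
  out <- structure(integer(length(annotation@genes)),
                   names = names(annotation@genes))
  out[names(w)] <- as.integer(w)
  out
}

#' Count reads per gene with intersection-nonempty semantics
#'
#' For each read, every aligned base collects the set of gene ids whose
#' features of \code{featureType} cover it; bases covered by no feature are
#' discarded; the remaining sets are intersected. A singleton intersection
#' counts the read for that gene. Reads with no covered base are
#' \code{no_feature}; a non-singleton result (several genes, or a read
#' split cleanly across two genes' features) is \code{ambiguous}. Multiple
#' isoforms of one gene never penalize a read, because sets contain gene
#' ids, not transcript ids.
#'
#' @param alignments \linkS4class{FootprintAlignments}.
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @param featureType feature to count over (default \code{"CDS"}).
#' @param stranded \code{"no"} (default), \code{"yes"} (read strand must
#'   match feature strand) or \code{"reverse"}.
#' @param mapqThreshold reads with MAPQ below this are \code{too_low_qual};
#'   0 (default) disables the filter.
#' @param sample sample label for the resulting column.
#' @return list: \code{counts} (named integer per gene, annotation order),
#'   \code{no_feature}, \code{ambiguous}, \code{too_low_qual},
#'   \code{reads_processed}, \code{sample}, \code{assignments} (per-read
#'   gene id, or \code{NA} with the reason in names).
#' @export
countReads <- function(alignments, annotation, featureType = "CDS",
                       stranded = c("no", "yes", "reverse"),
                       mapqThreshold = 0L, sample = "sample") {
  stranded <- match.arg(stranded)
  feats <- geneFeatures(annotation, featureType)
  genes <- names(annotation@genes)
  counts <- structure(integer(length(genes)), names = genes)
  nr <- nReads(alignments)
  assign <- rep(NA_character_, nr)
  reason <- rep(NA_character_, nr)
  lowq <- if (mapqThreshold > 0L)
    alignments@reads$mapq < mapqThreshold else rep(FALSE, nr)
  reason[lowq] <- "too_low_qual"
  b <- alignments@blocks
  keepBlock <- !lowq[mcols(b)$readIdx]
  b <- b[keepBlock]
  hits <- GenomicRanges::findOverlaps(b, feats, ignore.strand = TRUE)
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    if (stranded != "no") {
      rs <- as.character(strand(b))[qh]
      fs <- as.character(strand(feats))[sh]
      ok <- if (stranded == "yes") rs == fs else rs != fs
      qh <- qh[ok]; sh <- sh[ok]
    }
    if (length(qh)) {
      readIdx <- mcols(b)$readIdx[qh]
      perRead <- split(seq_along(qh), readIdx)
      for (rn in names(perRead)) {
        i <- as.integer(rn)
        sel <- perRead[[rn]]
        rBlocks <- IRanges::ranges(b)[qh[sel]]
        gids <- mcols(feats)$gene_id[sh[sel]]
        covered <- lapply(split(seq_along(sel), gids), function(k)
          IRanges::reduce(IRanges::pintersect(rBlocks[k],
                                              IRanges::ranges(feats)[sh[sel][k]])))
        unionCov <- IRanges::reduce(do.call(c, unname(covered)))
        full <- vapply(covered, sameRanges, logical(1), b = unionCov)
        winners <- names(covered)[full]
        if (length(winners) == 1L) assign[i] <- winners
        else reason[i] <- "ambiguous"
      }
    }
  }
  reason[is.na(assign) & is.na(reason)] <- "no_feature"
  tab <- table(assign[!is.na(assign)])
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       no_feature = sum(reason == "no_feature", na.rm = TRUE),
       ambiguous = sum(reason == "ambiguous", na.rm = TRUE),
       too_low_qual = sum(reason == "too_low_qual", na.rm = TRUE),
       reads_processed = nr,
       sample = sample,
       assignments = structure(assign, names = reason))
}

#' Assemble counted samples into a count matrix
#'
#' @param columns list of results from \code{\link{countReads}}, all counted
#'   against the same annotation.
#' @param annotation the \linkS4class{GenomeAnnotation} used for counting.
#' @param featureType feature type used; determines per-gene feature
#'   lengths (union across isoforms).
#' @return A \linkS4class{RiboCountMatrix}.
#' @export
assembleMatrix <- function(columns, annotation, featureType = "CDS") {
  genes <- names(annotation@genes)
  for (col in columns)
    if (!identical(names(col$counts), genes))
      stop("count column does not match annotation gene set (sample ",
           col$sample, ")")
  counts <- do.call(cbind, lapply(columns, `[[`, "counts"))
  colnames(counts) <- vapply(columns, `[[`, "", "sample")
  cd <- S4Vectors::DataFrame(
    no_feature = vapply(columns, `[[`, 1L, "no_feature"),
    ambiguous = vapply(columns, `[[`, 1L, "ambiguous"),
    too_low_qual = vapply(columns, `[[`, 1L, "too_low_qual"),
    reads_processed = vapply(columns, `[[`, 1L, "reads_processed"),
    row.names = colnames(counts))
  rd <- S4Vectors::DataFrame(
    featureLength = geneFeatureLengths(annotation, featureType),
    row.names = genes)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  metadata(se)$featureType <- featureType
  new("RiboCountMatrix", se)
}

#' @rdname RiboCountMatrix-class
#' @param x a \linkS4class{RiboCountMatrix}.
#' @export
countsMatrix <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname RiboCountMatrix-class
#' @export
featureLengths <- function(x) {
  structure(SummarizedExperiment::rowData(x)$featureLength,
            names = rownames(x))
}

#' @rdname RiboCountMatrix-class
#' @export
specialCounters <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Write a count table as HTSeq-style TSV
#'
#' Genes x samples, with trailing special-counter rows prefixed
#' \code{"__"}.
#'
#' @param x a \linkS4class{RiboCountMatrix}.
#' @param path output TSV path.
#' @export
writeCountTable <- function(x, path) {
  cts <- countsMatrix(x)
  sc <- specialCounters(x)
  extra <- rbind(`__no_feature` = sc$no_feature,
                 `__ambiguous` = sc$ambiguous,
                 `__too_low_qual` = sc$too_low_qual)
  colnames(extra) <- colnames(cts)
  out <- rbind(cts, extra)
  utils::write.table(data.frame(gene = rownames(out), out,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
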