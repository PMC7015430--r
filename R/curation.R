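#' Recursive CDS truncation of a transcript model
#'
#' Removes \code{trim5} nucleotides from the 5' end and \code{trim3} from the
#' 3' end of coding space, in transcript orientation (the 5' end is the
#' lowest genomic coordinate on \code{+}, the highest on \code{-}). The trim
#' recurses across the intron-split CDS segments: a terminal segment shorter
#' than the remaining trim is deleted whole and the remainder is taken from
#' the next segment. Exon records are never modified.
#'
#' Transcripts whose coding length is at most
#' \code{trim5 + trim3 + minRemaining} are returned unmodified with the flag
#' \code{"truncation_skipped"}; emitting zero- or near-zero-length CDS
#' records would be worse than leaving the pile-up regions in place.
#'
#' @param model \linkS4class{TranscriptModel} with at least one CDS segment
#'   (a model without CDS is returned unchanged with flag \code{"no_cds"}
#'   and a warning).
#' @param spec \linkS4class{TruncationSpec}.
#' @return The truncated \linkS4class{TranscriptModel}.
#' @examples
#' m <- new("TranscriptModel", transcriptId = "t1", geneId = "g1",
#'          chrom = "chr1", strand = "+", biotype = "protein_coding",
#'          exons = IRanges::IRanges(101, 400),
#'          cds = IRanges::IRanges(101, 400),
#'          canonical = TRUE, flags = character())
#' cdsRanges(truncateCDS(m, truncationSpec()))  # [146, 385]
#' @export
truncateCDS <- function(model, spec = truncationSpec()) {
  validObject(spec)
  if (!length(model@cds)) {
    warning("transcript ", model@transcriptId, " has no CDS; truncation is a no-op")
    model@flags <- union(model@flags, "no_cds")
    return(model)
  }
  len <- cdsLength(model)
  if (len <= spec@trim5 + spec@trim3 + spec@minRemaining) {
    model@flags <- union(model@flags, "truncation_skipped")
    return(model)
  }
  segs <- model@cds  # ascending genomic order
  if (model@strand == "+") {
    segs <- trimFront(segs, spec@trim5)
    segs <- trimBack(segs, spec@trim3)
  } else {
    segs <- trimBack(segs, spec@trim5)   # 5' end = highest coordinate
    segs <- trimFront(segs, spec@trim3)
  }
  model@cds <- segs
  model
}

# remove n coding bases from the lowest-coordinate end of ascending segments
trimFront <- function(segs, n) {
  while (n > 0L && length(segs)) {
    w <- width(segs)[1L]
    if (w <= n) {
      n <- n - w
      segs <- segs[-1L]
    } else {
      start(segs)[1L] <- start(segs)[1L] + n
      n <- 0L
    }
  }
  segs
}

# remove n coding bases from the highest-coordinate end
trimBack <- function(segs, n) {
  while (n > 0L && length(segs)) {
    k <- length(segs)
    w <- width(segs)[k]
    if (w <= n) {
      n <- n - w
      segs <- segs[-k]
    } else {
      end(segs)[k] <- end(segs)[k] - n
      n <- 0L
    }
  }
  segs
}

# GTF frame column for CDS segments given transcript order
cdsFrames <- function(segs, strand) {
  ord <- if (strand == "+") seq_along(segs) else rev(seq_along(segs))
  cum <- 0L
  frames <- integer(length(segs))
  for (i in ord) {
    frames[i] <- (3L - cum %% 3L) %% 3L
    cum <- cum + width(segs)[i]
  }
  frames
}

#' Retain only protein-coding gene records
#'
#' Keeps records whose gene (or, failing that, transcript) biotype is
#' \code{protein_coding}; gene and transcript maps are rebuilt. The number
#' of removed records is reported via \code{message()}.
#'
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @return Filtered \linkS4class{GenomeAnnotation}.
#' @export
filterProteinCoding <- function(annotation) {
  rec <- setDT(data.table::copy(annotation@records))
  gb <- gtfAttribute(rec$attributes, "gene_biotype")
  tb <- gtfAttribute(rec$attributes, "transcript_biotype")
  bio <- ifelse(is.na(gb), tb, gb)
  # a gene is protein_coding if any of its records says so
  pcGenes <- unique(rec$gene_id[!is.na(bio) & bio == "protein_coding"])
  keep <- rec$gene_id %in% pcGenes
  nDropped <- sum(!keep)
  if (nDropped) message(nDropped, " non-protein-coding record(s) removed")
  out <- rec[keep]
  if (!nrow(out)) warning("no protein_coding genes in annotation")
  suppressWarnings(buildAnnotation(out, annotation@comments))
}

#' Retain one canonical transcript per gene
#'
#' Keeps the transcript carrying the \code{Ensembl_canonical} tag when
#' present; otherwise the longest CDS, ties broken by longest exonic length,
#' then lexicographically smallest transcript id — a deterministic fallback
#' so curation output is reproducible. Gene-level records are retained.
#'
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @return Filtered \linkS4class{GenomeAnnotation}.
#' @export
selectCanonical <- function(annotation) {
  chosen <- vapply(annotation@genes, function(tids) {
    if (length(tids) == 1L) return(tids)
    ms <- annotation@transcripts[tids]
    canon <- vapply(ms, slot, logical(1), "canonical")
    if (any(canon)) tids <- tids[canon]
    ms <- annotation@transcripts[tids]
    cl <- vapply(ms, cdsLength, integer(1))
    el <- vapply(ms, exonicLength, integer(1))
    tids[order(-cl, -el, tids)][1L]
  }, character(1))
  rec <- setDT(data.table::copy(annotation@records))
  keep <- is.na(rec$transcript_id) | rec$transcript_id %in% chosen |
    rec$feature == "gene"
  suppressWarnings(buildAnnotation(rec[keep], annotation@comments))
}

# rewrite the CDS record rows of one transcript to the truncated segments;
# drops start_codon rows when trim5 >= 3 (the start codon is inside the
# trimmed region); stop_codon rows are outside the CDS and stay.
applyTruncationToRecords <- function(rec, model, spec) {
  isCds <- rec$feature == "CDS" & !is.na(rec$transcript_id) &
    rec$transcript_id == model@transcriptId
  cdsIdx <- which(isCds)[order(rec$start[which(isCds)])]
  segs <- model@cds
  drop <- integer()
  if (length(segs) && !"truncation_skipped" %in% model@flags) {
    frames <- cdsFrames(segs, model@strand)
    keepIdx <- cdsIdx[seq_along(segs)]
    rec$start[keepIdx] <- start(segs)
    rec$end[keepIdx] <- end(segs)
    rec$frame[keepIdx] <- as.character(frames)
    if (length(cdsIdx) > length(segs))
      drop <- cdsIdx[-seq_along(segs)]
    if (spec@trim5 >= 3L) {
      drop <- c(drop, which(rec$feature == "start_codon" &
                              !is.na(rec$transcript_id) &
                              rec$transcript_id == model@transcriptId))
    }
  }
  list(rec = rec, drop = drop)
}

#' Curate a GTF reference for ribosome-profiling quantification
#'
#' Applies, in order: protein-coding masking, canonical-transcript
#' selection, and recursive CDS truncation; then writes an Ensembl-dialect
#' GTF and returns a per-step curation report.
#'
#' @param gtfIn,gtfOut input/output GTF paths.
#' @param spec \linkS4class{TruncationSpec} used when \code{truncate} is TRUE.
#' @param proteinCoding,canonical,truncate logical step switches.
#' @return Invisibly, a list: the curated \linkS4class{GenomeAnnotation}
#'   (\code{annotation}), a data.frame of records in/out per step
#'   (\code{report}), and ids of transcripts skipped as too short
#'   (\code{skipped}).
#' @export
curateReference <- function(gtfIn, gtfOut, spec = truncationSpec(),
                            proteinCoding = TRUE, canonical = TRUE,
                            truncate = TRUE) {
  ann <- parseGTF(gtfIn)
  report <- data.frame(step = "input", records_in = nrow(ann@records),
                       records_out = nrow(ann@records))
  if (proteinCoding) {
    n0 <- nrow(ann@records)
    ann <- filterProteinCoding(ann)
    report <- rbind(report, data.frame(step = "protein_coding",
                                       records_in = n0,
                                       records_out = nrow(ann@records)))
  }
  if (canonical) {
    n0 <- nrow(ann@records)
    ann <- selectCanonical(ann)
    report <- rbind(report, data.frame(step = "canonical",
                                       records_in = n0,
                                       records_out = nrow(ann@records)))
  }
  skipped <- character()
  if (truncate) {
    n0 <- nrow(ann@records)
    rec <- setDT(data.table::copy(ann@records))
    dropAll <- integer()
    for (tid in names(ann@transcripts)) {
      m <- ann@transcripts[[tid]]
      if (!length(m@cds)) next
      mt <- truncateCDS(m, spec)
      if ("truncation_skipped" %in% mt@flags) {
        skipped <- c(skipped, tid)
        next
      }
      res <- applyTruncationToRecords(rec, mt, spec)
      rec <- res$rec
      dropAll <- c(dropAll, res$drop)
      ann@transcripts[[tid]] <- mt
    }
    if (length(dropAll)) rec <- rec[-unique(dropAll)]
    ann <- suppressWarnings(buildAnnotation(rec, ann@comments))
    # re-flag skipped transcripts lost in reassembly
    for (tid in skipped) {
      if (!is.null(ann@transcripts[[tid]]))
        ann@transcripts[[tid]]@flags <-
          union(ann@transcripts[[tid]]@flags, "truncation_skipped")
    }
    report <- rbind(report, data.frame(step = "truncate",
                                       records_in = n0,
                                       records_out = nrow(ann@records)))
  }
  writeGTF(ann, gtfOut)
  invisible(list(annotation = ann, report = report, skipped = skipped))
}
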