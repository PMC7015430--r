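#' @importFrom data.table data.table setDT rbindlist fread fwrite :=
NULL

GTF_COLS <- c("seqname", "source", "feature", "start", "end",
              "score", "strand", "frame", "attributes")

#' Extract one attribute from raw GTF attribute strings
#'
#' Ensembl dialect: \code{key "value"; } pairs. Returns \code{NA} where the
#' key is absent. GENCODE-style unquoted values are accepted on read.
#'
#' @param attrs character vector of raw attribute strings.
#' @param key attribute key, e.g. \code{"gene_id"}.
#' @return character vector of values (NA where absent).
#' @export
gtfAttribute <- function(attrs, key) {
  pat <- paste0("(^|; ?)", key, " \"?([^\";]*)\"?;")
  m <- regexpr(pat, attrs, perl = TRUE)
  out <- rep(NA_character_, length(attrs))
  hit <- m != -1L
  if (any(hit)) {
    out[hit] <- sub(pat, "\\2", regmatches(attrs, m)[seq_len(sum(hit))],
                    perl = TRUE)
  }
  out
}

# does the attribute string carry `tag "value"` (tags may repeat)?
hasGtfTag <- function(attrs, value) {
  grepl(paste0("tag \"", value, "\""), attrs, fixed = TRUE)
}

#' Parse a GTF annotation file
#'
#' Reads a 9-column tab-delimited GTF (Ensembl attribute dialect; GENCODE
#' accepted read-only), validates coordinates and required attributes, and
#' assembles one \linkS4class{TranscriptModel} per transcript. The raw
#' attribute strings are retained verbatim so \code{\link{writeGTF}}
#' round-trips byte-for-byte.
#'
#' Records with strand \code{"."} are kept in the record table but excluded
#' from transcript assembly (with a warning). \code{stop_codon} records are
#' never folded into CDS segments (Ensembl convention: the CDS excludes the
#' stop codon).
#'
#' @param path GTF file path.
#' @return A \linkS4class{GenomeAnnotation}.
#' @export
parseGTF <- function(path) {
  lines <- readLines(path)
  isComment <- startsWith(lines, "#")
  comments <- lines[isComment]
  body <- lines[!isComment]
  lineNo <- which(!isComment)
  if (!length(body)) {
    return(new("GenomeAnnotation",
               records = emptyGtfRecords(), transcripts = list(),
               genes = list(), comments = comments))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L)) {
    bad <- lineNo[which(nf != 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-delimited fields, got ",
         nf[which(nf != 9L)[1L]])
  }
  rec <- data.table(
    seqname    = vapply(parts, `[`, "", 1L),
    source     = vapply(parts, `[`, "", 2L),
    feature    = vapply(parts, `[`, "", 3L),
    start      = as.integer(vapply(parts, `[`, "", 4L)),
    end        = as.integer(vapply(parts, `[`, "", 5L)),
    score      = vapply(parts, `[`, "", 6L),
    strand     = vapply(parts, `[`, "", 7L),
    frame      = vapply(parts, `[`, "", 8L),
    attributes = vapply(parts, `[`, "", 9L),
    line       = lineNo
  )
  if (anyNA(rec$start) || anyNA(rec$end)) {
    bad <- rec$line[which(is.na(rec$start) | is.na(rec$end))[1L]]
    stop("malformed GTF line ", bad, ": non-numeric coordinate")
  }
  if (any(rec$end < rec$start)) {
    bad <- rec$line[which(rec$end < rec$start)[1L]]
    stop("invalid GTF line ", bad, ": end < start")
  }
  rec[, gene_id := gtfAttribute(attributes, "gene_id")]
  rec[, transcript_id := gtfAttribute(attributes, "transcript_id")]
  if (anyNA(rec$gene_id)) {
    bad <- rec$line[which(is.na(rec$gene_id))[1L]]
    stop("invalid GTF line ", bad, ": missing gene_id attribute")
  }
  needsTx <- !rec$feature %in% "gene"
  if (any(needsTx & is.na(rec$transcript_id))) {
    bad <- rec$line[which(needsTx & is.na(rec$transcript_id))[1L]]
    stop("invalid GTF line ", bad,
         ": missing transcript_id on a transcript-level record")
  }
  buildAnnotation(rec, comments)
}

emptyGtfRecords <- function() {
  data.table(seqname = character(), source = character(),
             feature = character(), start = integer(), end = integer(),
             score = character(), strand = character(), frame = character(),
             attributes = character(), line = integer(),
             gene_id = character(), transcript_id = character())
}

# assemble transcript models + gene map from a validated record table
buildAnnotation <- function(rec, comments = character()) {
  noStrand <- !rec$strand %in% c("+", "-")
  if (any(noStrand & !is.na(rec$transcript_id)))
    warning(sum(noStrand & !is.na(rec$transcript_id)),
            " record(s) with strand '.' excluded from transcript assembly")
  usable <- rec[!noStrand & !is.na(rec$transcript_id)]
  transcripts <- list()
  genes <- list()
  if (nrow(usable)) {
    for (tid in unique(usable$transcript_id)) {
      sub <- usable[usable$transcript_id == tid]
      exRows <- sub[sub$feature == "exon"]
      cdsRows <- sub[sub$feature == "CDS"]
      ord <- order(exRows$start)
      exons <- IRanges(exRows$start[ord], exRows$end[ord])
      ordc <- order(cdsRows$start)
      cds <- IRanges(cdsRows$start[ordc], cdsRows$end[ordc])
      biotype <- stats::na.omit(c(gtfAttribute(sub$attributes, "transcript_biotype"),
                                  gtfAttribute(sub$attributes, "gene_biotype")))
      flags <- character()
      if (!length(biotype)) flags <- "no_biotype"
      transcripts[[tid]] <- new("TranscriptModel",
        transcriptId = tid,
        geneId  = sub$gene_id[1L],
        chrom   = sub$seqname[1L],
        strand  = sub$strand[1L],
        biotype = if (length(biotype)) biotype[1L] else NA_character_,
        exons   = exons,
        cds     = cds,
        canonical = any(hasGtfTag(sub$attributes, "Ensembl_canonical")),
        flags   = flags)
      gid <- sub$gene_id[1L]
      genes[[gid]] <- c(genes[[gid]], tid)
    }
  }
  new("GenomeAnnotation", records = as.data.frame(rec),
      transcripts = transcripts, genes = genes, comments = comments)
}

#' Write a GenomeAnnotation back to GTF
#'
#' Emits header comments then one line per record in original order. Because
#' attribute strings are stored verbatim, an unmodified annotation
#' round-trips byte-identically; coordinate edits (e.g. truncation) change
#' only the start/end/frame fields of the affected records.
#'
#' @param annotation \linkS4class{GenomeAnnotation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGTF <- function(annotation, path) {
  rec <- annotation@records
  lines <- annotation@comments
  if (nrow(rec)) {
    lines <- c(lines, paste(rec$seqname, rec$source, rec$feature, rec$start,
                            rec$end, rec$score, rec$strand, rec$frame,
                            rec$attributes, sep = "\t"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a FASTA genome
#'
#' Sequences are uppercased and named by the first whitespace-delimited
#' header token. Duplicate names are an error.
#'
#' @param path FASTA file.
#' @return Named \link[Biostrings]{DNAStringSet}.
#' @export
readFasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence name in FASTA: ",
         names(seqs)[duplicated(names(seqs))][1L])
  Biostrings::DNAStringSet(toupper(seqs))
}

## ---- accessors ----

#' @rdname GenomeAnnotation-class
#' @param x,object a \linkS4class{GenomeAnnotation}.
#' @export
transcriptIds <- function(x) names(x@transcripts)

#' @rdname GenomeAnnotation-class
#' @export
geneIds <- function(x) names(x@genes)

#' @rdname GenomeAnnotation-class
#' @param id transcript id.
#' @export
getTranscript <- function(x, id) {
  tm <- x@transcripts[[id]]
  if (is.null(tm)) stop("unknown transcript: ", id)
  tm
}

#' @rdname GenomeAnnotation-class
#' @export
gtfRecords <- function(x) x@records

#' @rdname TranscriptModel-class
#' @param x a \linkS4class{TranscriptModel}.
#' @export
exonRanges <- function(x) x@exons

#' @rdname TranscriptModel-class
#' @export
cdsRanges <- function(x) x@cds

#' Total coding length (nt) of a transcript model
#' @param x a \linkS4class{TranscriptModel}.
#' @export
cdsLength <- function(x) sum(width(x@cds))

#' Total exonic length (nt) of a transcript model
#' @param x a \linkS4class{TranscriptModel}.
#' @export
exonicLength <- function(x) sum(width(x@exons))

setMethod("show", "GenomeAnnotation", function(object) {
  cat("GenomeAnnotation:", nrow(object@records), "records,",
      length(object@genes), "genes,", length(object@transcripts),
      "transcripts\n")
})

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel %s (gene %s) %s:%s | %d exon(s), %d nt; CDS %d nt%s\n",
              object@transcriptId, object@geneId, object@chrom, object@strand,
              length(object@exons), exonicLength(object), cdsLength(object),
              if (length(object@flags))
                paste0(" [", paste(object@flags, collapse = ","), "]")
              else ""))
})
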