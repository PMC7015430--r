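#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges start end width coverage
#' @importFrom GenomicRanges GRanges seqnames
NULL

#' Transcript model
#'
#' One transcript's exon and CDS structure: genomic exon intervals (pairwise
#' disjoint, ascending), CDS intervals (each contained in the exon union),
#' strand, biotype and the Ensembl-canonical flag. All intervals are 1-based
#' closed ([IRanges::IRanges]) on the genome; transcript orientation (5' to 3')
#' runs with increasing coordinates on \code{+} and decreasing on \code{-}.
#'
#' @slot transcriptId,geneId,chrom,strand,biotype character scalars; biotype
#'   may be \code{NA} when the source GTF carries no biotype attribute.
#' @slot exons,cds \linkS4class{IRanges} of genomic intervals, sorted
#'   ascending by start.
#' @slot canonical logical; \code{TRUE} when the transcript carries the
#'   \code{Ensembl_canonical} tag.
#' @slot flags character vector of processing flags (e.g.
#'   \code{"truncation_skipped"}, \code{"no_biotype"}).
#' @exportClass TranscriptModel
setClass("TranscriptModel", representation(
  transcriptId = "character",
  geneId       = "character",
  chrom        = "character",
  strand       = "character",
  biotype      = "character",
  exons        = "IRanges",
  cds          = "IRanges",
  canonical    = "logical",
  flags        = "character"
))

setValidity("TranscriptModel", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted ascending by start")
    if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be pairwise disjoint")
  }
  if (length(object@cds)) {
    uncovered <- IRanges::setdiff(object@cds, ex)
    if (length(uncovered))
      msg <- c(msg, sprintf("CDS bases outside exons in transcript %s",
                            object@transcriptId))
  }
  if (length(msg)) msg else TRUE
})

#' Genome annotation
#'
#' A parsed GTF: the verbatim record table (so that writing reproduces the
#' input byte-for-byte), assembled \linkS4class{TranscriptModel} objects, and
#' the gene-to-transcript map.
#'
#' @slot records data.frame with the nine GTF columns (attributes kept as the
#'   raw attribute string) plus extracted \code{gene_id}/\code{transcript_id}
#'   and the source line number.
#' @slot transcripts named list of \linkS4class{TranscriptModel}.
#' @slot genes named list: gene_id -> character vector of transcript ids.
#' @slot comments character; header comment lines, emitted first on write.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation", representation(
  records     = "data.frame",
  transcripts = "list",
  genes       = "list",
  comments    = "character"
))

setValidity("GenomeAnnotation", function(object) {
  tx <- unlist(object@genes, use.names = FALSE)
  if (anyDuplicated(tx))
    return("a transcript_id appears in more than one gene")
  if (!setequal(tx, names(object@transcripts)))
    return("gene map and transcript list disagree")
  TRUE
})

#' CDS truncation parameters
#'
#' @slot trim5,trim3 nucleotides removed from the 5'/3' ends of coding space
#'   (defaults 45 and 15, the ribosome-profiling convention excluding
#'   initiation and termination pile-ups).
#' @slot minRemaining minimum coding nucleotides that must remain for
#'   truncation to apply (default 3 = one codon); transcripts with coding
#'   length <= trim5 + trim3 + minRemaining are left untouched and flagged.
#' @exportClass TruncationSpec
setClass("TruncationSpec", representation(
  trim5        = "integer",
  trim3        = "integer",
  minRemaining = "integer"
))

setValidity("TruncationSpec", function(object) {
  msg <- character()
  if (object@trim5 < 0L || object@trim3 < 0L)
    msg <- c(msg, "trim amounts must be non-negative")
  if (object@minRemaining < 3L || object@minRemaining %% 3L != 0L)
    msg <- c(msg, "minRemaining must be >= 3 and divisible by 3")
  if (length(msg)) msg else TRUE
})

#' @param trim5,trim3,minRemaining see slot documentation.
#' @rdname TruncationSpec-class
#' @export
truncationSpec <- function(trim5 = 45L, trim3 = 15L, minRemaining = 3L) {
  new("TruncationSpec", trim5 = as.integer(trim5), trim3 = as.integer(trim3),
      minRemaining = as.integer(minRemaining))
}

#' Aligned reads
#'
#' Parsed SAM alignments: one row per read in \code{reads}, and the flattened
#' aligned genomic blocks (CIGAR M/=/X/D; N introduces gaps) in \code{blocks},
#' linked by the integer \code{readIdx} metadata column.
#'
#' @slot reads data.frame: readId, chrom, strand, pos5 (strand-aware 5'-most
#'   aligned position), readLength (aligned query length), mapq, flag, umi,
#'   duplicate (NA until \code{\link{markDuplicates}} runs).
#' @slot blocks \linkS4class{GRanges} of aligned blocks with mcol
#'   \code{readIdx}.
#' @exportClass FootprintAlignments
setClass("FootprintAlignments", representation(
  reads  = "data.frame",
  blocks = "GRanges"
))

setValidity("FootprintAlignments", function(object) {
  idx <- mcols(object@blocks)$readIdx
  if (length(object@blocks) && (is.null(idx) || max(idx) > nrow(object@reads)))
    return("blocks readIdx out of range")
  TRUE
})

#' Per-position coverage track
#'
#' @slot space \code{"genomic"} or \code{"exonic"} (intron-collapsed
#'   transcript coordinates, position 1 = transcript 5' end).
#' @slot ref reference identifier (chromosome or transcript id).
#' @slot offset genomic coordinate of the first position (1 for exonic).
#' @slot counts non-negative integer vector.
#' @exportClass CoverageTrack
setClass("CoverageTrack", representation(
  space  = "character",
  ref    = "character",
  offset = "integer",
  counts = "integer"
))

setValidity("CoverageTrack", function(object) {
  if (any(object@counts < 0L)) return("counts must be non-negative")
  if (!object@space %in% c("genomic", "exonic"))
    return("space must be 'genomic' or 'exonic'")
  TRUE
})

#' Exon-space coordinate map
#'
#' Bijection between a transcript's genomic exon positions and intron-
#' collapsed exon-space positions 1..L, where position 1 is the transcript's
#' 5' end (the highest genomic coordinate on \code{-} strand).
#'
#' @slot transcriptId character.
#' @slot genomicPos integer, ascending genomic positions of all exonic bases.
#' @slot exonicPos integer, parallel exon-space positions.
#' @exportClass ExonCoordinateMap
setClass("ExonCoordinateMap", representation(
  transcriptId = "character",
  genomicPos   = "integer",
  exonicPos    = "integer"
))

setValidity("ExonCoordinateMap", function(object) {
  if (length(object@genomicPos) != length(object@exonicPos))
    return("genomicPos and exonicPos must be parallel")
  if (anyDuplicated(object@exonicPos)) return("map must be bijective")
  TRUE
})

#' Metagene profile
#'
#' Fixed-bin, per-transcript-normalized read-start coverage averaged with
#' equal weight across transcripts, so highly expressed transcripts cannot
#' dominate the profile.
#'
#' @slot bins numeric vector of length B summing to 1 (when any transcript
#'   contributed).
#' @slot nTranscripts transcripts that passed the coverage threshold.
#' @slot nExcluded transcripts below the threshold.
#' @slot label sample label.
#' @exportClass MetageneProfile
setClass("MetageneProfile", representation(
  bins         = "numeric",
  nTranscripts = "integer",
  nExcluded    = "integer",
  label        = "character"
))

setValidity("MetageneProfile", function(object) {
  if (any(object@bins < 0)) return("bins must be non-negative")
  if (object@nTranscripts > 0L && abs(sum(object@bins) - 1) > 1e-8)
    return("bins must sum to 1")
  TRUE
})

#' Codon phasing profile
#'
#' P-site positions of footprints relative to annotated start codons: the
#' reading-frame counts, the start-relative P-site histogram, and the
#' per-read-length 5'-end offsets used.
#'
#' @slot frameCounts integer of length 3, names "0","1","2"; P-sites within
#'   the CDS by coding frame.
#' @slot startHistogram named integer over start-relative positions -50..150.
#' @slot offsets named integer, P-site offset per read length.
#' @slot offsetMode "auto" or "fixed".
#' @exportClass PhasingProfile
setClass("PhasingProfile", representation(
  frameCounts    = "integer",
  startHistogram = "integer",
  offsets        = "integer",
  offsetMode     = "character"
))

#' Count matrix with counting diagnostics
#'
#' A \linkS4class{SummarizedExperiment} holding the integer \code{counts}
#' assay, per-gene feature lengths in \code{rowData(x)$featureLength}, and
#' the HTSeq-style special counters (\code{no_feature}, \code{ambiguous},
#' \code{too_low_qual}, \code{reads_processed}) in \code{colData}.
#'
#' @exportClass RiboCountMatrix
setClass("RiboCountMatrix", contains = "SummarizedExperiment")

setValidity("RiboCountMatrix", function(object) {
  cts <- SummarizedExperiment::assay(object, "counts")
  if (any(cts < 0)) return("counts must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("no_feature", "ambiguous", "too_low_qual", "reads_processed")
  if (!all(need %in% colnames(cd)))
    return(paste("colData must contain", paste(need, collapse = ", ")))
  tot <- colSums(cts) + cd$no_feature + cd$ambiguous + cd$too_low_qual
  if (any(tot != cd$reads_processed))
    return("per-sample counts + special counters must equal reads processed")
  TRUE
})

#' Translation-efficiency table
#'
#' Per-gene, per-condition log2 translation efficiency: TPM-normalized
#' footprint abundance over TPM-normalized mRNA abundance with a small
#' pseudocount, replicates averaged on the log2 scale (geometric mean of
#' ratios).
#'
#' @slot log2TE numeric matrix, genes x conditions.
#' @slot pseudocount numeric, the constant added to both TPM values.
#' @exportClass TETable
setClass("TETable", representation(
  log2TE      = "matrix",
  pseudocount = "numeric"
))

#' TE screen result
#'
#' Gene lists from the fold-change thresholding paradigm: genes whose TE
#' drops (or rises) at least \code{fcThreshold}-fold under stress, and the
#' subsets restored (or suppressed) at least \code{fcThreshold}-fold by the
#' co-treatment.
#'
#' @slot upInStress,downInStress,restoredByCotreatment,suppressedByCotreatment
#'   character vectors of gene ids.
#' @slot fcThreshold numeric fold-change threshold.
#' @slot deltas numeric matrix, genes x contrasts, of log2 TE changes.
#' @exportClass ScreenResult
setClass("ScreenResult", representation(
  upInStress              = "character",
  downInStress            = "character",
  restoredByCotreatment   = "character",
  suppressedByCotreatment = "character",
  fcThreshold             = "numeric",
  deltas                  = "matrix"
))
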