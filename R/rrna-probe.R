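#' Over-represented sequences in a trimmed footprint FASTQ
#'
#' Exact-sequence counting: a sequence is retained when its count is at
#' least \code{minFraction} of the library (inclusive) and its length is at
#' least \code{minLen}. Inputs are expected to be adaptor- and quality-
#' trimmed already; no mismatch tolerance is applied (candidate identity is
#' checked downstream by the user against rRNA references).
#'
#' @param fastq FASTQ path (gzip accepted).
#' @param minFraction minimum count / total-reads fraction (default 0.001,
#'   the usual over-representation convention).
#' @param minLen minimum sequence length (default 17, the lower edge of the
#'   footprint window).
#' @return Named integer vector of counts, descending.
#' @export
overrepresentedSequences <- function(fastq, minFraction = 0.001,
                                     minLen = 17L) {
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  if (!length(reads)) {
    warning("empty FASTQ: ", fastq)
    return(structure(integer(0), names = character(0)))
  }
  total <- length(reads)
  tab <- table(as.character(reads))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  keep <- counts / total >= minFraction & nchar(names(counts)) >= minLen
  sort(counts[keep], decreasing = TRUE)
}

#' Merge conserved sequences across samples into probe candidates
#'
#' Two sequences are merged when one is an exact substring of the other;
#' merging is the transitive closure of that relation. Each group is
#' represented by its longest member (ties: lexicographically smallest) and
#' accumulates the counts of all members, preserving per-sample counts.
#' Reverse complements are not merged by default (depletion probes are
#' strand-specific).
#'
#' @param perSampleMaps named list of named count vectors, one per sample
#'   (as returned by \code{\link{overrepresentedSequences}}).
#' @param mergeRevcomp also merge a sequence with substrings of its reverse
#'   complement (default FALSE).
#' @return data.frame: sequence, total_count, n_samples, and one
#'   count column per sample.
#' @export
mergeConserved <- function(perSampleMaps, mergeRevcomp = FALSE) {
  if (!length(perSampleMaps)) stop("at least one sample map required")
  if (is.null(names(perSampleMaps)))
    names(perSampleMaps) <- paste0("sample", seq_along(perSampleMaps))
  seqs <- sort(unique(unlist(lapply(perSampleMaps, names))))
  n <- length(seqs)
  if (!n) {
    out <- data.frame(sequence = character(), total_count = integer(),
                      n_samples = integer(), stringsAsFactors = FALSE)
    for (s in names(perSampleMaps)) out[[s]] <- integer(0)
    return(out)
  }
  # union-find over the substring relation (transitive closure)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  targets <- seqs
  if (mergeRevcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      hit <- grepl(seqs[i], targets[j], fixed = TRUE) ||
        (mergeRevcomp && grepl(rc[i], targets[j], fixed = TRUE))
      if (hit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), comp)
  rows <- lapply(groups, function(idx) {
    members <- seqs[idx]
    rep <- members[order(-nchar(members), members)][1L]
    perSample <- vapply(perSampleMaps, function(m)
      sum(m[names(m) %in% members]), 1L)
    data.frame(sequence = rep, total_count = sum(perSample),
               n_samples = sum(vapply(perSampleMaps, function(m)
                 any(names(m) %in% members), logical(1))),
               t(perSample), stringsAsFactors = FALSE, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank probe candidates
#'
#' Orders by total count descending, ties by the number of samples where the
#' sequence is over-represented (descending), then lexicographically; adds a
#' 1-based \code{rank} column and optionally writes a TSV.
#'
#' @param candidates data.frame from \code{\link{mergeConserved}}.
#' @param path optional TSV output path.
#' @return The ranked data.frame.
#' @export
rankProbes <- function(candidates, path = NULL) {
  ord <- order(-candidates$total_count, -candidates$n_samples,
               candidates$sequence)
  out <- candidates[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out
}

#' End-to-end rRNA probe candidate design
#'
#' Counts over-represented sequences per FASTQ, merges conserved sequences
#' across the experiment, and returns the rank-ordered candidate list for
#' subtractive-hybridization probe design.
#'
#' @param fastqs character vector of FASTQ paths (names become sample
#'   labels; basenames are used otherwise).
#' @param minFraction,minLen see \code{\link{overrepresentedSequences}}.
#' @param mergeRevcomp see \code{\link{mergeConserved}}.
#' @param path optional TSV output path.
#' @return Ranked candidate data.frame.
#' @export
rrnaProbe <- function(fastqs, minFraction = 0.001, minLen = 17L,
                      mergeRevcomp = FALSE, path = NULL) {
  if (is.null(names(fastqs)))
    names(fastqs) <- sub("\\.f(ast)?q(\\.gz)?$", "", basename(fastqs))
  maps <- lapply(fastqs, overrepresentedSequences,
                 minFraction = minFraction, minLen = minLen)
  rankProbes(mergeConserved(maps, mergeRevcomp = mergeRevcomp), path = path)
}
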