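#' Low-count gene filter on RNA-seq counts
#'
#' A gene is kept only when every RNA sample has at least \code{minCount}
#' counts (the boundary is inclusive: a gene at exactly the threshold
#' stays).
#'
#' @param rna \linkS4class{RiboCountMatrix} or integer matrix
#'   (genes x samples).
#' @param minCount minimum per-sample count (default 10).
#' @return Named logical mask over genes.
#' @export
lowCountFilter <- function(rna, minCount = 10L) {
  cts <- if (is(rna, "RiboCountMatrix")) countsMatrix(rna) else as.matrix(rna)
  structure(apply(cts >= minCount, 1L, all), names = rownames(cts))
}

#' Translation efficiency from paired footprint / RNA counts
#'
#' TPM-normalizes each matrix independently, computes per sample
#' te = (footprint TPM + pc) / (RNA TPM + pc) with pseudocount
#' \code{pc}, and averages log2(te) across replicates within each condition
#' (the geometric mean of ratios, symmetric in the up/down direction).
#' This is a descriptive estimator for fold-change screening; count-model
#' statistical testing (e.g. a negative-binomial interaction test) is
#' deliberately out of scope and can be attached via
#' \code{\link{applyFdrFilter}}.
#'
#' @param rpf,rna \linkS4class{RiboCountMatrix} or integer matrices with
#'   identical gene sets; columns are samples.
#' @param conditions named character: condition label per sample (names
#'   must cover the columns of both matrices).
#' @param lengths per-gene feature lengths, required when matrices are
#'   plain (taken from the objects otherwise).
#' @param pseudocount constant added to both TPM values (default 0.01).
#' @return A \linkS4class{TETable}.
#' @export
translationEfficiency <- function(rpf, rna, conditions, lengths = NULL,
                                  pseudocount = 0.01) {
  rpfC <- if (is(rpf, "RiboCountMatrix")) countsMatrix(rpf) else as.matrix(rpf)
  rnaC <- if (is(rna, "RiboCountMatrix")) countsMatrix(rna) else as.matrix(rna)
  if (!identical(rownames(rpfC), rownames(rnaC))) {
    bad <- utils::head(c(setdiff(rownames(rpfC), rownames(rnaC)),
                         setdiff(rownames(rnaC), rownames(rpfC))), 10L)
    stop("gene sets differ between footprint and RNA matrices: ",
         paste(bad, collapse = ", "))
  }
  missing <- setdiff(c(colnames(rpfC), colnames(rnaC)), names(conditions))
  if (length(missing))
    stop("no condition label for sample(s): ", paste(missing, collapse = ", "))
  if (is.null(lengths) && is(rpf, "RiboCountMatrix"))
    lengths <- featureLengths(rpf)
  rpfT <- normalizedMatrix(normalizeCounts(rpfC, "tpm", lengths = lengths))
  rnaT <- normalizedMatrix(normalizeCounts(rnaC, "tpm", lengths = lengths))
  conds <- sort(unique(conditions))
  log2TE <- vapply(conds, function(cond) {
    rpfS <- names(conditions)[conditions == cond & names(conditions) %in%
                                colnames(rpfT)]
    rnaS <- names(conditions)[conditions == cond & names(conditions) %in%
                                colnames(rnaT)]
    if (!length(rpfS) || !length(rnaS))
      stop("condition '", cond, "' lacks footprint or RNA samples")
    # pair replicates positionally; unequal replicate numbers use the mean
    # of per-assay log2 averages, which reduces to the same value when
    # paired
    lr <- rowMeans(log2(rpfT[, rpfS, drop = FALSE] + pseudocount))
    ln <- rowMeans(log2(rnaT[, rnaS, drop = FALSE] + pseudocount))
    lr - ln
  }, numeric(nrow(rpfC)))
  log2TE <- matrix(log2TE, nrow = nrow(rpfC),
                   dimnames = list(rownames(rpfC), conds))
  new("TETable", log2TE = log2TE, pseudocount = pseudocount)
}

#' @rdname TETable-class
#' @param x a \linkS4class{TETable}.
#' @export
log2TE <- function(x) x@log2TE

#' Change in log2 translation efficiency between two conditions
#'
#' @param x \linkS4class{TETable}.
#' @param condition,reference condition labels; the result is
#'   log2TE(condition) - log2TE(reference), antisymmetric under swapping.
#' @return Named numeric vector over genes.
#' @export
deltaLog2TE <- function(x, condition, reference) {
  for (c in c(condition, reference))
    if (!c %in% colnames(x@log2TE)) stop("unknown condition: ", c)
  structure(x@log2TE[, condition] - x@log2TE[, reference],
            names = rownames(x@log2TE))
}

setMethod("show", "TETable", function(object) {
  cat("TETable:", nrow(object@log2TE), "genes x",
      ncol(object@log2TE), "conditions (pseudocount",
      object@pseudocount, ")\n")
})

#' Fold-change TE screen
#'
#' The strict thresholding paradigm: a gene is \code{downInStress} when its
#' TE under stress drops to at most 1/\code{fcThreshold} of the untreated
#' TE, and \code{restoredByCotreatment} when it is down in stress and the
#' co-treatment raises TE at least \code{fcThreshold}-fold over stress;
#' \code{upInStress}/\code{suppressedByCotreatment} are the mirror
#' definitions.
#'
#' @param te \linkS4class{TETable}.
#' @param stress,reference,cotreatment condition labels for the two
#'   contrasts (stress vs reference; cotreatment vs stress).
#' @param fcThreshold fold-change threshold (default 2).
#' @return A \linkS4class{ScreenResult}.
#' @export
screenTE <- function(te, stress, reference, cotreatment, fcThreshold = 2) {
  d1 <- deltaLog2TE(te, stress, reference)
  d2 <- deltaLog2TE(te, cotreatment, stress)
  lt <- log2(fcThreshold)
  down <- names(d1)[d1 <= -lt]
  up <- names(d1)[d1 >= lt]
  restored <- down[d2[down] >= lt]
  suppressed <- up[d2[up] <= -lt]
  new("ScreenResult",
      upInStress = up, downInStress = down,
      restoredByCotreatment = restored,
      suppressedByCotreatment = suppressed,
      fcThreshold = fcThreshold,
      deltas = cbind(stress_vs_reference = d1, cotreat_vs_stress = d2))
}

#' @rdname ScreenResult-class
#' @param x a \linkS4class{ScreenResult}.
#' @param category one of \code{"up_in_stress"}, \code{"down_in_stress"},
#'   \code{"restored_by_cotreatment"}, \code{"suppressed_by_cotreatment"}.
#' @export
screenGenes <- function(x, category = c("restored_by_cotreatment",
                                        "down_in_stress", "up_in_stress",
                                        "suppressed_by_cotreatment")) {
  switch(match.arg(category),
         up_in_stress = x@upInStress,
         down_in_stress = x@downInStress,
         restored_by_cotreatment = x@restoredByCotreatment,
         suppressed_by_cotreatment = x@suppressedByCotreatment)
}

setMethod("show", "ScreenResult", function(object) {
  cat(sprintf(paste0("ScreenResult (fold-change threshold %.2g): ",
                     "%d up / %d down in stress; %d restored, ",
                     "%d suppressed by co-treatment\n"),
              object@fcThreshold, length(object@upInStress),
              length(object@downInStress),
              length(object@restoredByCotreatment),
              length(object@suppressedByCotreatment)))
})

#' Optional FDR filter on externally supplied per-gene statistics
#'
#' When a per-gene p-value table from a count-model test is available, keeps
#' genes with |log2 fold change| above \code{lfcThreshold} and
#' Benjamini-Hochberg adjusted p-value below \code{fdr}.
#'
#' @param genes character vector of candidate genes (e.g. from
#'   \code{\link{screenGenes}}).
#' @param stats data.frame with columns \code{gene}, \code{log2fc},
#'   \code{pvalue}.
#' @param lfcThreshold minimum |log2 fold change| (default 1).
#' @param fdr BH-adjusted p-value cutoff (default 0.1).
#' @return Filtered gene vector.
#' @export
applyFdrFilter <- function(genes, stats, lfcThreshold = 1, fdr = 0.1) {
  stats$padj <- stats::p.adjust(stats$pvalue, method = "BH")
  pass <- stats$gene[abs(stats$log2fc) > lfcThreshold & stats$padj < fdr]
  intersect(genes, pass)
}
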