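#' Normalize a count matrix (RPM, RPKM/FPKM, TPM)
#'
#' Per sample s with counts c_gs and feature lengths L_g (nt):
#' \deqn{rpm = c_{gs} 10^6 / \sum_g c_{gs}}
#' \deqn{rpkm = c_{gs} 10^9 / (L_g \sum_g c_{gs})}
#' \deqn{tpm = (c_{gs}/L_g) 10^6 / \sum_g (c_{gs}/L_g)}
#' FPKM equals RPKM here (single-end fragment semantics). The per-sample
#' denominator is the counted-gene total: special counters
#' (\code{__no_feature} etc.) never enter normalization.
#'
#' @param x a \linkS4class{RiboCountMatrix}, or a plain numeric matrix
#'   (genes x samples) with \code{lengths} supplied.
#' @param method one of \code{"tpm"}, \code{"rpm"}, \code{"rpkm"},
#'   \code{"fpkm"}.
#' @param lengths per-gene feature lengths in nt; taken from \code{x} when
#'   it is a \linkS4class{RiboCountMatrix}.
#' @return A \linkS4class{SummarizedExperiment} with one real-valued assay
#'   named after the method (\code{metadata()$method} records it); row and
#'   column annotation are carried over when present.
#' @export
normalizeCounts <- function(x, method = c("tpm", "rpm", "rpkm", "fpkm"),
                            lengths = NULL) {
  method <- match.arg(method)
  if (is(x, "RiboCountMatrix")) {
    cts <- countsMatrix(x)
    if (is.null(lengths)) lengths <- featureLengths(x)
  } else {
    cts <- as.matrix(x)
  }
  needLen <- method %in% c("rpkm", "fpkm", "tpm")
  if (needLen) {
    if (is.null(lengths))
      stop("method '", method, "' requires per-gene feature lengths")
    lengths <- lengths[rownames(cts)]
    if (anyNA(lengths) || any(lengths <= 0))
      stop("zero or missing feature length for gene(s): ",
           paste(utils::head(rownames(cts)[is.na(lengths) | lengths <= 0], 10L),
                 collapse = ", "))
  }
  libSize <- colSums(cts)
  if (any(libSize == 0))
    warning("all-zero sample(s): ",
            paste(colnames(cts)[libSize == 0], collapse = ", "))
  norm <- switch(method,
    rpm = sweep(cts, 2L, pmax(libSize, 1), "/") * 1e6,
    rpkm = ,
    fpkm = sweep(cts / lengths, 2L, pmax(libSize, 1), "/") * 1e9,
    tpm = {
      rate <- cts / lengths
      sweep(rate, 2L, pmax(colSums(rate), .Machine$double.xmin), "/") * 1e6
    })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = stats::setNames(list(norm), method))
  metadata(se)$method <- method
  se
}

#' Extract the normalized matrix from a normalization result
#' @param x result of \code{\link{normalizeCounts}}.
#' @export
normalizedMatrix <- function(x) SummarizedExperiment::assay(x, 1L)
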