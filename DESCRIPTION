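Package: riboprof
Title: Reference Curation, Quality Control and Translation-Efficiency
    Screening for Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the bespoke computational stages of ribosome
    profiling analysis: recursive CDS truncation of GTF annotations,
    protein-coding masking and canonical-transcript selection, metagene
    and intron-collapsed gene coverage profiles, codon-phasing (P-site
    offset) estimation, rank-ordered rRNA depletion probe candidates from
    over-represented footprint sequences, intersection-nonempty read
    counting, RPM/RPKM/FPKM/TPM normalization, duplication-rate library
    complexity metrics, and a fold-change translation-efficiency screen.
    A deterministic simulator generates genome, annotation and read
    fixtures with full ground truth for every quantity the package
    estimates.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomicAlignments,
    Biostrings,
    SummarizedExperiment,
    data.table
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
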