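---
title: "Methods: curation, QC and TE screening for ribosome profiling"
author: "riboprof"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, QC and TE screening for ribosome profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboprof)
```

## The problem

Ribosome profiling reads are short (17–33 nt) footprints of translating
ribosomes. Between alignment and inference sit several steps that decide
whether downstream translation-efficiency estimates mean anything:
which annotation positions count as quantifiable coding space, how reads
are assigned to genes, how library pathologies (rRNA contamination, PCR
duplication, end pile-ups) are detected, and how footprint abundance is
related to mRNA abundance. This package implements those steps as
testable, deterministic operations over standard formats (Ensembl-dialect
GTF, FASTA, SAM, FASTQ, TSV count tables).

## Coordinate conventions

On disk, GTF coordinates are 1-based inclusive. Internally every interval
is an `IRanges` (1-based, closed), the Bioconductor convention; all
arithmetic (trimming, intersection, union, coverage) goes through IRanges
operations, so no hand-written ±1 adjustments exist anywhere in the code.
Exon space ("intron-collapsed" transcript coordinates) runs 1..L with
position 1 at the transcript's 5' end — the lowest genomic exonic
coordinate on `+`, the highest on `-`. The exon map is an explicit
bijection and is property-tested for round-trip identity on both strands.

The GTF parser keeps each record's raw attribute string verbatim. This is
deliberate: the curation stage rewrites annotation files, and a curated
file should differ from its input only where curation changed coordinates.
Round-trip identity (parse, write, byte-compare) is asserted in the tests.
GENCODE-style attribute syntax is accepted on input; output is always
Ensembl style. Records with strand `.` stay in the file but are excluded
from transcript assembly with a warning, and `stop_codon` records are
never folded into the CDS (Ensembl convention: the CDS excludes the stop
codon).

## Recursive CDS truncation

Initiation and termination pile-ups are excluded from quantification by
removing, by default, 45 nt from the 5' end and 15 nt from the 3' end of
each transcript's *coding space* (45 nt ≈ 15 codons of initiation context;
both defaults are multiples of 3, so reading frames are preserved).
Because the CDS is split across exons, trimming recurses: walk the CDS
segments in transcript orientation, delete any terminal segment shorter
than the remaining trim, and take the remainder from the next segment.

Choices the trimming rule leaves open, and what this package does:

- **Short CDS.** A transcript whose coding length is at most
  `trim5 + trim3 + minRemaining` (default 45 + 15 + 3) is left untouched
  and flagged `truncation_skipped`. Emitting zero- or near-zero-length CDS
  records would silently produce degenerate quantification targets; an
  explicit flag plus an unmodified record is recoverable.
- **Exon records are never modified.** Truncation redefines the
  quantified feature (CDS), not the transcript structure; UTR records are
  likewise untouched, so UTR-targeted quantification still sees the
  original annotation.
- **`start_codon` records are dropped** once `trim5 >= 3` (the start codon
  is inside the removed region); `stop_codon` records are retained (they
  lie outside the CDS).
- **Frames are recomputed** from the truncated coding walk:
  `frame = (3 - cumulative_coding mod 3) mod 3` along transcript order.

Truncation is verified against a base-by-base oracle (enumerate coding
positions, drop the first 45 and last 15, reassemble) on hundreds of
randomized multi-segment models on both strands, plus a strand-mirroring
property.

Canonical-transcript selection keeps the `Ensembl_canonical`-tagged
transcript when present. When the tag is absent the fallback is
deterministic — longest CDS, then longest exonic length, then smallest
transcript id — because curation output must be reproducible across runs
and annotation versions. Protein-coding masking keeps every record of
genes with a `protein_coding` biotype (gene-level first, transcript-level
as fallback). The pipeline order is fixed and logged: mask, select
canonical, truncate.

## Alignment model

SAM text is the parsing surface (the simulator emits SAM, and SAM is what
the tests inspect). CIGAR semantics: `M/=/X` consume and cover the
reference; `D` consumes and is counted as covered; `N` splits aligned
blocks; `S` and `I` consume query only. Unmapped, secondary and
supplementary records are excluded by default. MAPQ filtering is off by
default (multimap policy belongs to the aligner). UMIs, when requested,
are taken from the read-name suffix after the last underscore — the common
post-extraction encoding.

## Metagene and phasing

The metagene profile answers "where along transcripts do reads sit?".
Each read contributes one unit at its 5'-most exon-space position on every
transcript it overlaps by at least one aligned base (the profile is
descriptive QC, not quantification, so multi-transcript attribution
maximizes stability). Per transcript, positional counts are binned into
`bins` (default 100) near-equal bins — position p of a length-L transcript
goes to bin `floor(B*(p-1)/L)+1`, so uniform-coverage expectations of
`1/B` carry a ±1-position binning tolerance — and divided by the
transcript's total. Transcripts with fewer than `minCoverage` (default 10)
reads are excluded and counted. The equal-weight average across
transcripts makes the profile invariant to any one transcript's depth:
multiplying one transcript's reads 100-fold leaves the combined profile
bit-identical, which the tests assert literally.

Codon phasing estimates, per read length, the offset from a footprint's
5' end to its ribosomal P-site. In `auto` mode the offset is the modal
distance from 5' ends to annotated start codons over reads whose 5' end
falls within −50..0 of a start; read lengths with fewer than 30 such
reads inherit the global modal offset, and if no start-proximal reads
exist at all the fixed offset (default 16 nt, a mid-range footprint value)
is used with a warning. P-sites are then `5' end + offset` in transcript
orientation; frames are `(P-site − CDS start) mod 3`, counted for P-sites
inside the CDS, and the start-relative histogram spans −50..+150.

## rRNA probe candidates

A handful of RNase-resistant rRNA fragments can dominate footprint
libraries. Candidates are exact sequences whose count is at least
`minFraction` (default 0.001, inclusive) of a library and at least
`minLen` (default 17 nt, the lower footprint bound) long. Across samples,
sequences are merged when one is an exact substring of another (transitive
closure; the longest member represents the group, ties broken
lexicographically), and candidates are ranked by total count, then
breadth of sample support, then sequence. Exact matching is deliberate:
the input is already trimmed, fragment identity is confirmed downstream
by the user, and fuzzy clustering would make counts unauditable. Reverse
complements are not merged by default because depletion probes are
strand-specific. The merge is tested against an O(n²) all-pairs closure
oracle and for count conservation and sample-order invariance.

## Counting

Intersection-nonempty, gene-level: for each read, every aligned base
collects the set of gene ids whose features (default `CDS`; `exon` and the
UTR types work the same way) cover it; bases covered by nothing are
discarded; the remaining sets are intersected. A singleton result counts
the read for that gene; no covered base at all is `__no_feature`; anything
else — several genes covering everything, or a read split cleanly between
two genes — is `__ambiguous`. Sets hold gene ids, not transcript ids, so a
read consistent with several isoforms of one gene is never penalized.
Feature lengths are per-gene union lengths across isoforms. The
implementation works on interval intersections but is defined — and
tested, on 1000-read fixtures — by the per-base brute force, including the
exact conservation identity
`counts + no_feature + ambiguous + too_low_qual = reads processed`.
Counting is unstranded by default (`stranded = "yes"/"reverse"` available).

## Normalization

For counts $c_{gs}$ and feature lengths $L_g$ (nt):
$\mathrm{rpm} = 10^6 c_{gs} / \sum_g c_{gs}$,
$\mathrm{rpkm} = 10^9 c_{gs} / (L_g \sum_g c_{gs})$,
$\mathrm{tpm} = 10^6 (c_{gs}/L_g) / \sum_g (c_{gs}/L_g)$; FPKM equals RPKM
under single-end semantics. The denominator is always the counted-gene
total — the `__`-prefixed counters never enter it. TPM columns summing to
10^6 and scale invariance are asserted at 10^-6 relative tolerance.

## Duplication and complexity

Duplicate groups share (chromosome, strand, strand-aware 5' position,
aligned length), plus the UMI when available. Keying on 5' position and
length rather than the full block structure is the robust choice for
footprint-length reads, where a 1-nt CIGAR difference almost always
reflects alignment noise rather than a distinct molecule; it diverges from
tools that key on the full CIGAR, and the divergence is documented here.
One representative per group (highest MAPQ, then smallest read id) stays
unflagged. Quantification keeps duplicates by default — footprint
libraries have legitimate positional duplicates, and removal would be
overly stringent — the flags feed only the complexity table: per gene,
total and unique reads, duplication rate `1 − unique/total`, and
expression as reads per kilobase of feature length.

## Translation-efficiency screen

TE here is descriptive:
$\log_2\!\frac{\mathrm{TPM_{RPF}} + 0.01}{\mathrm{TPM_{RNA}} + 0.01}$,
replicates averaged on the log2 scale (the geometric mean of ratios, so up-
and down-regulation are symmetric). The pseudocount 0.01 on the TPM scale
is small enough to distort genes above ~50 TPM by far less than the screen
threshold while keeping ratios finite. Count-model inference (a
negative-binomial interaction test) is intentionally out of scope; when an
external per-gene p-value table exists, `applyFdrFilter()` applies
|log2 fold change| > 1 with Benjamini–Hochberg FDR < 0.1.

Genes are pre-filtered by requiring every RNA sample to have at least 10
counts (inclusive). The screen itself is threshold arithmetic: a gene is
"down in stress" when TE(stress)/TE(reference) ≤ 1/fc, and "restored" when
it is down and TE(cotreatment)/TE(stress) ≥ fc, with mirror-image "up" and
"suppressed" categories; fc defaults to 2. Raising fc can only shrink
categories — asserted as a subset property.

## The simulator

The simulator defines the study conditions every test runs under, with
ground truth for each estimated quantity. Multi-exon genes on both
strands carry Ensembl-style records (biotypes, canonical tags, start/stop
codons patched into the genome sequence); per-gene expression is lognormal
(sdlog 0.5 around a mean of 200 weight units); footprint lengths follow a
discrete triangular distribution over 17–33 nt peaked at 28; footprints
are placed with their P-site (5' end + a true offset, default 12 nt) in
frame 0 of the CDS; RNA-assay reads are uniform over the transcript.
Initiation/termination pile-ups are multiplicative elevations over the
first 45 / last 15 coding nt whose strength decays geometrically (ratio
0.5 per codon) from the terminal codon — an initiation peak with queued
ribosomes behind it, which is what makes the modal-offset estimator
identifiable. PCR duplicates are exact copies (same coordinates and UMI)
added at a configured rate; rRNA contaminants are exact fragment copies
appearing in the FASTQ only, at a configured fraction of sequenced reads
(default scenario for probe tests: 3 fragments at 85%). SAM records are
the ground-truth alignments; no aligner runs. Everything is
byte-deterministic under a fixed seed, with the caller's RNG state
restored.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: sequencing errors and quality variation,
multimapping and alignment ambiguity, overlapping genes and antisense
transcription, isoform diversity within genes (one transcript per
simulated gene), nucleotide-composition bias, and the count-overdispersion
structure of real biological replicates (noise is lognormal with a single
CV). The estimators' contracts (oracle equivalence, conservation
identities, invariances) transfer to real data; the recovery accuracies
measured on simulations need not.

## Problem sizes and numerical choices

The test suite uses 3–8 genes, 300–8000 reads per library, 200 randomized
truncation models, 1000-read counting-oracle fixtures, 1200-read
duplication fixtures, and a 2000-gene / 20-hit TE screen — sizes at which
every oracle comparison is exhaustive and the whole suite runs in a few
minutes on one CPU. Ties in canonical selection, probe ranking and
duplicate representatives are all broken lexicographically after the
scientific criteria, so outputs are stable across platforms. Degenerate
inputs (no CDS, empty libraries, all-zero samples, zero-length features)
warn or error by contract rather than propagating NaNs; the tests pin each
of those behaviors.
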