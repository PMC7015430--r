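test_that("intersection-nonempty classifies the canonical read placements", {
  ann <- parseGTF(twoGeneGtf())
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, rbind(
    samRead("inside_A", 120L, "30M"),       # fully inside gA only
    samRead("boundary", 170L, "50M"),       # bases exclusive to gA AND to gB
    samRead("half_out", 90L, "30M"),        # half intergenic, half gA
    samRead("overlapA", 190L, "25M"),       # in gA/gB overlap + gB-only
    samRead("intergenic", 300L, "30M")))
  res <- countReads(parseSAM(sam), ann, featureType = "CDS")
  expect_identical(res$counts, c(gA = 2L, gB = 1L))
  expect_identical(res$ambiguous, 1L)       # boundary read
  expect_identical(res$no_feature, 1L)      # intergenic read
  # overlapA: bases 190..200 in {A,B}, 201..214 in {B} -> intersection {B}
  expect_identical(unname(res$assignments[4L]), "gB")
  # conservation identity
  expect_identical(sum(res$counts) + res$no_feature + res$ambiguous +
                     res$too_low_qual, res$reads_processed)
})

test_that("a read over two isoforms of one gene is not penalized", {
  a1 <- 'gene_id "g"; transcript_id "t1"; gene_biotype "protein_coding";'
  a2 <- 'gene_id "g"; transcript_id "t2"; gene_biotype "protein_coding";'
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(gtf, c(
    gtfLine("transcript", 1, 300, attrs = a1),
    gtfLine("exon", 1, 300, attrs = a1),
    gtfLine("CDS", 1, 150, attrs = a1, frame = "0"),
    gtfLine("transcript", 1, 300, attrs = a2),
    gtfLine("exon", 1, 300, attrs = a2),
    gtfLine("CDS", 100, 300, attrs = a2, frame = "0")))
  ann <- parseGTF(gtf)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, samRead("r", 140L, "30M"))  # spans both isoform CDS sets
  res <- countReads(parseSAM(sam), ann, featureType = "CDS")
  expect_identical(res$counts, c(g = 1L))
  expect_identical(res$ambiguous, 0L)
})

test_that("unknown feature types are rejected with the available list", {
  ann <- parseGTF(twoGeneGtf())
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, samRead("r", 120L, "10M"))
  expect_error(countReads(parseSAM(sam), ann, featureType = "bogus"),
               "CDS")
})

test_that("counting matches the per-base brute-force oracle on a 1000-read fixture", {
  cfg <- simulationConfig(seed = 61, nGenes = 6, readsPerSample = 1000)
  dir <- withr::local_tempdir()
  ref <- simulateReference(cfg, dir)
  ann <- parseGTF(ref$gtf)
  rd <- simulateReads(cfg, ref, dir, sample = "s", assay = "rpf")
  aln <- parseSAM(rd$sam)
  res <- countReads(aln, ann, featureType = "CDS")

  featTable <- gtfRecords(ann)
  featTable <- featTable[featTable$feature == "CDS",
                         c("gene_id", "start", "end")]
  b <- alignedBlocks(aln)
  blockList <- lapply(seq_len(nReads(aln)), function(i) {
    x <- b[S4Vectors::mcols(b)$readIdx == i]
    cbind(GenomicRanges::start(x), GenomicRanges::end(x))
  })
  want <- bruteAssign(blockList, featTable)
  expect_identical(unname(res$counts[names(res$counts)]),
                   vapply(names(res$counts), function(g)
                     sum(want == g), 1L, USE.NAMES = FALSE))
  expect_identical(res$no_feature, sum(want == "__no_feature"))
  expect_identical(res$ambiguous, sum(want == "__ambiguous"))
  expect_identical(sum(res$counts) + res$no_feature + res$ambiguous,
                   res$reads_processed)
})

test_that("matrix assembly orders genes, takes union lengths, handles empty samples", {
  ann <- parseGTF(twoGeneGtf())
  sam1 <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam1, rbind(samRead("r1", 120L, "30M"),
                       samRead("r2", 240L, "30M")))
  samEmpty <- withr::local_tempfile(fileext = ".sam")
  writeSam(samEmpty, samRead("r", 400L, "30M"))
  cols <- list(countReads(parseSAM(sam1), ann, "CDS", sample = "s1"),
               countReads(parseSAM(samEmpty), ann, "CDS", sample = "s2"))
  cm <- assembleMatrix(cols, ann, "CDS")
  expect_identical(rownames(cm), c("gA", "gB"))
  expect_identical(unname(countsMatrix(cm)[, "s2"]), c(0L, 0L))
  expect_identical(specialCounters(cm)["s2", "no_feature"], 1L)
  expect_identical(unname(featureLengths(cm)), c(100L, 100L))

  # overlapping isoforms: union length, not sum
  a1 <- 'gene_id "g"; transcript_id "t1";'
  a2 <- 'gene_id "g"; transcript_id "t2";'
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(gtf, c(
    gtfLine("transcript", 1, 300, attrs = a1),
    gtfLine("exon", 1, 300, attrs = a1),
    gtfLine("CDS", 1, 200, attrs = a1, frame = "0"),
    gtfLine("transcript", 1, 300, attrs = a2),
    gtfLine("exon", 1, 300, attrs = a2),
    gtfLine("CDS", 101, 300, attrs = a2, frame = "0")))
  ann2 <- parseGTF(gtf)
  col <- countReads(parseSAM(sam1), ann2, "CDS", sample = "s1")
  cm2 <- assembleMatrix(list(col), ann2, "CDS")
  expect_identical(unname(featureLengths(cm2)), 300L)
})

test_that("counting over a truncated annotation excludes 5' pile-up reads", {
  cfg <- simulationConfig(seed = 62, nGenes = 5, readsPerSample = 2000,
                          pileup5Factor = 10)
  dir <- withr::local_tempdir()
  ref <- simulateReference(cfg, dir)
  curated <- file.path(dir, "curated.gtf")
  suppressMessages(curateReference(ref$gtf, curated))
  rd <- simulateReads(cfg, ref, dir, sample = "s", assay = "rpf")
  aln <- parseSAM(rd$sam)
  full <- countReads(aln, parseGTF(ref$gtf), "CDS")
  trunc <- countReads(aln, parseGTF(curated), "CDS")
  expect_lt(sum(trunc$counts), sum(full$counts))
  expect_gt(trunc$no_feature, full$no_feature)
})

test_that("count tables round-trip through the HTSeq-style TSV writer", {
  ann <- parseGTF(twoGeneGtf())
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, rbind(samRead("r1", 120L, "30M"),
                      samRead("r2", 300L, "30M")))
  cm <- assembleMatrix(list(countReads(parseSAM(sam), ann, "CDS",
                                       sample = "s1")), ann, "CDS")
  out <- withr::local_tempfile(fileext = ".tsv")
  writeCountTable(cm, out)
  tab <- utils::read.delim(out)
  expect_identical(tab$gene, c("gA", "gB", "__no_feature", "__ambiguous",
                               "__too_low_qual"))
  expect_identical(tab$s1, c(1L, 0L, 1L, 0L, 0L))
})
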