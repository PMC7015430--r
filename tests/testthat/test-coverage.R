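test_that("exon maps concatenate exons and respect strand orientation", {
  # single exon, + strand: identity up to the exon offset
  m <- makeModel(ir(1, 100), strand = "+")
  map <- buildExonMap(m)
  expect_identical(genomicToExonic(map, 1L), 1L)
  expect_identical(genomicToExonic(map, 100L), 100L)

  # two exons [1,10], [21,30], + strand: first base of exon 2 is position 11
  m2 <- makeModel(ir(c(1, 21), c(10, 30)))
  map2 <- buildExonMap(m2)
  expect_identical(genomicToExonic(map2, 21L), 11L)
  expect_identical(exonicToGenomic(map2, 11L), 21L)
  expect_identical(exonicSpan(map2), 20L)

  # same exons, - strand: the transcript 5' end is the highest coordinate
  m3 <- makeModel(ir(c(1, 21), c(10, 30)), strand = "-")
  map3 <- buildExonMap(m3)
  expect_identical(genomicToExonic(map3, 30L), 1L)
  expect_identical(genomicToExonic(map3, 1L), 20L)
})

test_that("exon maps are bijective on random transcripts", {
  set.seed(5)
  for (i in 1:40) {
    m <- randomCdsModel()
    map <- buildExonMap(m)
    L <- exonicSpan(m |> buildExonMap())
    # round-trip identity both ways
    expect_identical(genomicToExonic(map, exonicToGenomic(map, 1:L)), 1:L)
    g <- sort(map@genomicPos)
    expect_identical(exonicToGenomic(map, genomicToExonic(map, g)), g)
  }
})

test_that("gene coverage collapses introns and reports CDS bounds in exon space", {
  attrs <- 'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(gtf, c(
    gtfLine("gene", 1, 400, attrs = 'gene_id "g1"; gene_biotype "protein_coding";'),
    gtfLine("transcript", 1, 400, attrs = attrs),
    gtfLine("exon", 1, 100, attrs = attrs),
    gtfLine("exon", 301, 400, attrs = attrs),
    gtfLine("CDS", 31, 100, attrs = attrs, frame = "0"),
    gtfLine("CDS", 301, 360, attrs = attrs, frame = "0")))
  ann <- parseGTF(gtf)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, rbind(
    samRead("exonic", 91L, "10M200N10M"),   # spans the intron
    samRead("intronic", 150L, "30M")))       # entirely in the intron
  aln <- parseSAM(sam)
  gc <- geneCoverage(aln, ann, "g1")
  counts <- trackCounts(gc$track)
  expect_identical(length(counts), 200L)
  expect_identical(counts[91:110], rep(1L, 20))  # contiguous in exon space
  expect_identical(sum(counts), 20L)             # intronic read contributes 0
  expect_identical(gc$cdsStart, 31L)
  expect_identical(gc$cdsEnd, 160L)
  expect_error(geneCoverage(aln, ann, "nope"), "nope")
})

test_that("metagene bins sum to one and match closed forms", {
  attrs1 <- 'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'
  attrs2 <- 'gene_id "g2"; transcript_id "t2"; gene_biotype "protein_coding";'
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(gtf, c(
    gtfLine("gene", 1, 200, attrs = 'gene_id "g1";'),
    gtfLine("transcript", 1, 200, attrs = attrs1),
    gtfLine("exon", 1, 200, attrs = attrs1),
    gtfLine("gene", 1001, 1200, attrs = 'gene_id "g2";'),
    gtfLine("transcript", 1001, 1200, attrs = attrs2),
    gtfLine("exon", 1001, 1200, attrs = attrs2)))
  ann <- parseGTF(gtf)
  # t1: one read starting at every position of its first half
  # t2: one read at every position of the whole transcript
  reads <- rbind(
    do.call(rbind, lapply(1:100, function(p)
      samRead(paste0("a", p), p, "20M"))),
    do.call(rbind, lapply(1001:1180, function(p)
      samRead(paste0("b", p), p, "20M"))))
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, reads)
  aln <- parseSAM(sam)
  prof <- metagene(aln, ann, bins = 10L)
  expect_equal(sum(profileBins(prof)), 1)
  # t1 contributes 2/B over bins 1..5, 0 after; t2 is flat-ish over 1..9
  b <- profileBins(prof)
  expect_true(all(b[1:5] > b[6:10]))
  # half-covered transcript alone: exactly 2/B on the first half
  profHalf <- metagene(subsetReads(aln, 1:100), ann, bins = 10L,
                       minCoverage = 1L)
  expect_equal(profileBins(profHalf)[1:5], rep(0.2, 5))
  expect_equal(profileBins(profHalf)[6:10], rep(0, 5))
})

test_that("per-transcript normalization damps super-expressors bit-identically", {
  cfg <- simulationConfig(seed = 41, nGenes = 4, readsPerSample = 400)
  dir <- withr::local_tempdir()
  ref <- simulateReference(cfg, dir)
  ann <- parseGTF(ref$gtf)
  rd <- simulateReads(cfg, ref, dir, sample = "s", assay = "rna")
  aln <- parseSAM(rd$sam)
  base <- metagene(aln, ann, minCoverage = 1L)
  # replicate every read of one gene 100x by concatenating SAM body lines
  lines <- readLines(rd$sam)
  body <- lines[!startsWith(lines, "@")]
  g1reads <- body[grepl(paste(rd$truth$readId[rd$truth$gene == "G01"],
                              collapse = "|"), body)]
  boosted <- withr::local_tempfile(fileext = ".sam")
  writeLines(c(lines, rep(g1reads, 99L)), boosted)
  alnBoost <- parseSAM(boosted)
  expect_identical(profileBins(metagene(alnBoost, ann, minCoverage = 1L)),
                   profileBins(base))
})

test_that("transcripts below the coverage threshold are excluded with a count", {
  attrs <- 'gene_id "g1"; transcript_id "t1";'
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(gtf, c(gtfLine("transcript", 1, 100, attrs = attrs),
                      gtfLine("exon", 1, 100, attrs = attrs)))
  ann <- parseGTF(gtf)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, samRead("r1", 1L, "20M"))
  aln <- parseSAM(sam)
  expect_warning(prof <- metagene(aln, ann, minCoverage = 10L),
                 "no transcript")
  expect_identical(prof@nTranscripts, 0L)
  expect_identical(prof@nExcluded, 1L)
})

test_that("phasing recovers a planted P-site offset and frame concentration", {
  cfg <- simulationConfig(seed = 42, nGenes = 8, pileup5Factor = 8,
                          readsPerSample = 6000, pSiteOffset = 12L)
  dir <- withr::local_tempdir()
  ref <- simulateReference(cfg, dir)
  ann <- parseGTF(ref$gtf)
  rd <- simulateReads(cfg, ref, dir, sample = "s", assay = "rpf")
  ph <- phasing(parseSAM(rd$sam), ann)
  fc <- frameCounts(ph)
  expect_gt(fc["0"] / sum(fc), 0.95)
  # majority of per-length offsets within 1 nt of truth
  offs <- psiteOffsets(ph)
  expect_identical(as.integer(stats::median(offs)), 12L)
  # start-relative histogram peaks at the initiation codon
  h <- startHistogram(ph)
  expect_identical(names(which.max(h)), "0")
})

test_that("uniformly placed reads give near-uniform frames", {
  cfg <- simulationConfig(seed = 43, nGenes = 5, readsPerSample = 3000)
  dir <- withr::local_tempdir()
  ref <- simulateReference(cfg, dir)
  ann <- parseGTF(ref$gtf)
  rd <- simulateReads(cfg, ref, dir, sample = "s", assay = "rna")
  ph <- phasing(parseSAM(rd$sam), ann, offsetMode = "fixed",
                fixedOffset = 16L)
  fc <- frameCounts(ph)
  expect_gt(stats::chisq.test(fc)$p.value, 0.01)
})

test_that("a read starting at the start codon with zero offset is frame 0 at position 0", {
  attrs <- 'gene_id "g1"; transcript_id "t1";'
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(gtf, c(gtfLine("transcript", 1, 200, attrs = attrs),
                      gtfLine("exon", 1, 200, attrs = attrs),
                      gtfLine("CDS", 51, 150, attrs = attrs, frame = "0")))
  ann <- parseGTF(gtf)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeSam(sam, samRead("r1", 51L, "28M"))
  ph <- phasing(parseSAM(sam), ann, offsetMode = "fixed", fixedOffset = 0L)
  expect_identical(unname(frameCounts(ph)), c(1L, 0L, 0L))
  h <- startHistogram(ph)
  expect_identical(unname(h["0"]), 1L)
  expect_identical(sum(h), 1L)
})
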