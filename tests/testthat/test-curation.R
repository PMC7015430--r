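test_that("default truncation trims 45 nt from the 5' side and 15 from the 3' side", {
  m <- makeModel(ir(101, 400), ir(101, 400))
  out <- truncateCDS(m, truncationSpec())
  expect_identical(IRanges::start(cdsRanges(out)), 146L)
  expect_identical(IRanges::end(cdsRanges(out)), 385L)
  expect_identical(cdsLength(out), 240L)
})

test_that("zero trim is the identity", {
  m <- makeModel(ir(c(101, 201), c(130, 400)), ir(c(101, 201), c(130, 400)))
  out <- truncateCDS(m, truncationSpec(0, 0))
  expect_identical(cdsRanges(out), cdsRanges(m))
})

test_that("trimming recurses across segments, deleting short terminal segments", {
  m <- makeModel(ir(c(101, 201), c(130, 400)), ir(c(101, 201), c(130, 400)))
  out <- truncateCDS(m, truncationSpec(trim5 = 45, trim3 = 0))
  expect_identical(length(cdsRanges(out)), 1L)
  expect_identical(IRanges::start(cdsRanges(out)), 216L)
  expect_identical(IRanges::end(cdsRanges(out)), 400L)
  expect_identical(cdsRanges(out),
                   bruteTruncate(cdsRanges(m), "+", 45L, 0L))
})

test_that("minus-strand trimming removes the 5' amount from the high-coordinate end", {
  m <- makeModel(ir(101, 400), ir(101, 400), strand = "-")
  out <- truncateCDS(m, truncationSpec())
  expect_identical(IRanges::start(cdsRanges(out)), 116L)
  expect_identical(IRanges::end(cdsRanges(out)), 355L)
})

test_that("short CDS transcripts are skipped and flagged, never zero-length", {
  m <- makeModel(ir(101, 160), ir(101, 150))  # 50 nt <= 45 + 15 + 3
  out <- truncateCDS(m, truncationSpec())
  expect_identical(cdsRanges(out), cdsRanges(m))
  expect_true("truncation_skipped" %in% out@flags)
  expect_warning(out2 <- truncateCDS(makeModel(ir(1, 100))), "no CDS")
  expect_true("no_cds" %in% out2@flags)
})

test_that("interval truncation equals the base-by-base oracle on random models", {
  set.seed(42)
  for (i in 1:200) {
    m <- randomCdsModel()
    spec <- truncationSpec(sample(0:60, 1), sample(0:30, 1))
    got <- cdsRanges(truncateCDS(m, spec))
    want <- bruteTruncate(cdsRanges(m), m@strand, spec@trim5, spec@trim3)
    expect_identical(got, want)
  }
})

test_that("truncation is strand-symmetric and conserves coding length", {
  set.seed(7)
  for (i in 1:50) {
    m <- randomCdsModel(strand = "+")
    len <- cdsLength(m)
    spec <- truncationSpec()
    out <- truncateCDS(m, spec)
    if (!"truncation_skipped" %in% out@flags) {
      expect_identical(cdsLength(out), len - 60L)
      # containment: no new coordinates invented
      expect_length(IRanges::setdiff(cdsRanges(out), cdsRanges(m)), 0L)
    }
    # mirror the model around a fixed point; trimming the - strand mirror
    # must mirror the + strand trim
    M <- 100000L
    mirror <- makeModel(
      rev(ir(M - IRanges::end(m@exons), M - IRanges::start(m@exons))),
      rev(ir(M - IRanges::end(m@cds), M - IRanges::start(m@cds))),
      strand = "-")
    outM <- truncateCDS(mirror, spec)
    back <- rev(ir(M - IRanges::end(cdsRanges(outM)),
                   M - IRanges::start(cdsRanges(outM))))
    expect_identical(back, cdsRanges(out))
  }
})

test_that("protein-coding masking keeps protein-coding genes and is idempotent", {
  ref <- simulateReference(simulationConfig(seed = 21, nGenes = 3,
                                            nRrnaGenes = 2),
                           withr::local_tempdir())
  ann <- parseGTF(ref$gtf)
  expect_length(geneIds(ann), 5L)
  f1 <- suppressMessages(filterProteinCoding(ann))
  expect_identical(sort(geneIds(f1)), c("G01", "G02", "G03"))
  f2 <- suppressMessages(filterProteinCoding(f1))
  expect_identical(gtfRecords(f2), gtfRecords(f1))
  expect_warning(
    suppressMessages(filterProteinCoding(
      parseGTF(writeTinyGtf(withr::local_tempfile(fileext = ".gtf"), c(
        gtfLine("gene", 1, 100, attrs = 'gene_id "r1"; gene_biotype "rRNA";')))))),
    "no protein_coding")
})

test_that("canonical selection prefers the tag, then CDS length, deterministically", {
  a1 <- 'gene_id "g1"; transcript_id "t1"; transcript_biotype "protein_coding";'
  a2 <- paste(a1, 'tag "Ensembl_canonical";')
  a3 <- sub("t1", "t2", a1)
  path <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(path, c(
    gtfLine("transcript", 1, 1000, attrs = a2),
    gtfLine("exon", 1, 1000, attrs = a2),
    gtfLine("CDS", 1, 150, attrs = a2, frame = "0"),
    gtfLine("transcript", 1, 2000, attrs = a3),
    gtfLine("exon", 1, 2000, attrs = a3),
    gtfLine("CDS", 1, 300, attrs = a3, frame = "0")))
  ann <- parseGTF(path)
  expect_identical(transcriptIds(selectCanonical(ann)), "t1")  # tag wins

  # untagged: longest CDS wins
  writeTinyGtf(path, c(
    gtfLine("transcript", 1, 1000, attrs = a1),
    gtfLine("exon", 1, 1000, attrs = a1),
    gtfLine("CDS", 1, 150, attrs = a1, frame = "0"),
    gtfLine("transcript", 1, 2000, attrs = a3),
    gtfLine("exon", 1, 2000, attrs = a3),
    gtfLine("CDS", 1, 300, attrs = a3, frame = "0")))
  ann <- parseGTF(path)
  sel <- selectCanonical(ann)
  expect_identical(transcriptIds(sel), "t2")
  # idempotent
  expect_identical(gtfRecords(selectCanonical(sel)), gtfRecords(sel))
})

test_that("full curation reduces every eligible coding length by exactly 60", {
  ref <- simulateReference(simulationConfig(seed = 22, nGenes = 6,
                                            nRrnaGenes = 2),
                           withr::local_tempdir())
  out <- withr::local_tempfile(fileext = ".gtf")
  res <- suppressMessages(curateReference(ref$gtf, out))
  before <- parseGTF(ref$gtf)
  after <- parseGTF(out)
  expect_length(geneIds(after), 6L)  # rRNA genes masked
  for (tid in transcriptIds(after)) {
    if (tid %in% res$skipped) next
    expect_identical(cdsLength(getTranscript(after, tid)),
                     cdsLength(getTranscript(before, tid)) - 60L)
    # exon records untouched
    expect_identical(exonRanges(getTranscript(after, tid)),
                     exonRanges(getTranscript(before, tid)))
  }
})

test_that("curation with all steps off writes an identical body", {
  ref <- simulateReference(simulationConfig(seed = 23, nGenes = 3),
                           withr::local_tempdir())
  out <- withr::local_tempfile(fileext = ".gtf")
  curateReference(ref$gtf, out, proteinCoding = FALSE, canonical = FALSE,
                  truncate = FALSE)
  expect_identical(readLines(out), readLines(ref$gtf))
})

test_that("a 50-nt CDS survives curation unmodified but flagged", {
  attrs <- 'gene_id "g1"; transcript_id "t1"; gene_biotype "protein_coding";'
  path <- withr::local_tempfile(fileext = ".gtf")
  writeTinyGtf(path, c(
    gtfLine("gene", 1, 200, attrs = 'gene_id "g1"; gene_biotype "protein_coding";'),
    gtfLine("transcript", 1, 200, attrs = attrs),
    gtfLine("exon", 1, 200, attrs = attrs),
    gtfLine("CDS", 51, 100, attrs = attrs, frame = "0")))
  out <- withr::local_tempfile(fileext = ".gtf")
  res <- suppressMessages(curateReference(path, out))
  expect_identical(res$skipped, "t1")
  expect_identical(cdsRanges(getTranscript(parseGTF(out), "t1")), ir(51, 100))
})
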