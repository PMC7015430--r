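#' Simulation parameters
#'
#' Defines the synthetic study conditions: gene architecture, the footprint
#' length distribution (discrete triangular over 17-33 nt peaked at 28, the
#' captured ribosome-footprint window), the true P-site offset, optional
#' coverage pile-ups over the first/last coding nucleotides (the
#' initiation/termination artifact that CDS truncation excludes), rRNA
#' contamination, PCR duplication, and expression/TE structure.
#'
#' @param seed RNG seed; fixed seed gives byte-identical outputs.
#' @param nGenes protein-coding genes.
#' @param nRrnaGenes additional single-exon rRNA-biotype genes.
#' @param exonsPerGene integer range (min, max) of exons per transcript.
#' @param cdsCodons range of CDS length in codons.
#' @param utr5Range,utr3Range UTR length ranges (nt).
#' @param intronRange intron length range (nt).
#' @param footprintLengths candidate footprint lengths (nt).
#' @param footprintPeak mode of the triangular length distribution.
#' @param pSiteOffset true distance from footprint 5' end to P-site (nt).
#' @param pileup5Factor,pileup3Factor multiplicative read-density elevation
#'   over the first \code{pileupWindow5} / last \code{pileupWindow3} coding
#'   nt (1 = flat).
#' @param pileupWindow5,pileupWindow3 window sizes in nt (defaults 45/15,
#'   matching the default truncation).
#' @param rrnaFragments character vector of contaminant sequences.
#' @param contaminationFraction fraction of sequenced reads drawn from the
#'   contaminant fragments.
#' @param duplicationRate fraction of reads that are PCR duplicates.
#' @param umis attach random 8-mer UMIs to read names.
#' @param readsPerSample genic reads per library.
#' @param meanExpression mean per-gene expression weight.
#' @param replicates replicates per condition (TE simulation).
#' @param noiseCV lognormal coefficient of variation on per-sample
#'   expression (TE simulation).
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(seed = 1L, nGenes = 5L, nRrnaGenes = 0L,
                             exonsPerGene = c(1L, 4L),
                             cdsCodons = c(60L, 200L),
                             utr5Range = c(20L, 100L),
                             utr3Range = c(20L, 100L),
                             intronRange = c(50L, 200L),
                             footprintLengths = 17:33,
                             footprintPeak = 28L,
                             pSiteOffset = 12L,
                             pileup5Factor = 1, pileup3Factor = 1,
                             pileupWindow5 = 45L, pileupWindow3 = 15L,
                             rrnaFragments = character(),
                             contaminationFraction = 0,
                             duplicationRate = 0,
                             umis = FALSE,
                             readsPerSample = 2000L,
                             meanExpression = 200,
                             replicates = 3L,
                             noiseCV = 0.2) {
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              nRrnaGenes = as.integer(nRrnaGenes),
              exonsPerGene = as.integer(exonsPerGene),
              cdsCodons = as.integer(cdsCodons),
              utr5Range = as.integer(utr5Range),
              utr3Range = as.integer(utr3Range),
              intronRange = as.integer(intronRange),
              footprintLengths = as.integer(footprintLengths),
              footprintPeak = as.integer(footprintPeak),
              pSiteOffset = as.integer(pSiteOffset),
              pileup5Factor = pileup5Factor, pileup3Factor = pileup3Factor,
              pileupWindow5 = as.integer(pileupWindow5),
              pileupWindow3 = as.integer(pileupWindow3),
              rrnaFragments = rrnaFragments,
              contaminationFraction = contaminationFraction,
              duplicationRate = duplicationRate,
              umis = umis,
              readsPerSample = as.integer(readsPerSample),
              meanExpression = meanExpression,
              replicates = as.integer(replicates),
              noiseCV = noiseCV)
  for (f in c("contaminationFraction", "duplicationRate"))
    if (cfg[[f]] < 0 || cfg[[f]] >= 1)
      stop(f, " must be in [0, 1)")
  if (cfg$contaminationFraction > 0 && !length(cfg$rrnaFragments))
    stop("contaminationFraction > 0 requires rrnaFragments")
  class(cfg) <- "SimulationConfig"
  cfg
}

# run expr under a derived seed, restoring the caller's RNG state
withSimSeed <- function(seed, offset, expr) {
  had <- exists(".Random.seed", envir = globalenv())
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed((seed * 1000L + offset) %% .Machine$integer.max)
  expr
}

randInt <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

# place codon bases on the forward genomic strand
patchCodon <- function(chars, positions, codon, strand) {
  bases <- strsplit(codon, "")[[1L]]
  if (strand == "-") bases <- rev(chartr("ACGT", "TGCA", bases))
  chars[positions] <- bases
  chars
}

#' Generate a synthetic genome and annotation with ground truth
#'
#' Writes an Ensembl-dialect GTF (gene/transcript/exon/CDS/start_codon/
#' stop_codon/UTR records, canonical tags, biotypes), a FASTA genome with
#' real start/stop codons, and a per-transcript ground-truth TSV. Both
#' strands are represented; rRNA-biotype genes are single-exon with no
#' CDS.
#'
#' @param config \code{\link{simulationConfig}}.
#' @param dir output directory (created if needed).
#' @return list: \code{fasta}, \code{gtf}, \code{truthFile} paths;
#'   \code{truth} data.frame; \code{models} named list of
#'   \linkS4class{TranscriptModel} (ground truth, built independently of
#'   the GTF parser).
#' @export
simulateReference <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  withSimSeed(config$seed, 1L, {
    nTotal <- config$nGenes + config$nRrnaGenes
    cursor <- 1L
    recs <- list()
    models <- list()
    truth <- list()
    chars <- character(0)  # genome assembled after layout
    patches <- list()
    for (g in seq_len(nTotal)) {
      isRrna <- g > config$nGenes
      gid <- if (isRrna) sprintf("RRNA%02d", g - config$nGenes)
             else sprintf("G%02d", g)
      tid <- paste0(gid, ".T1")
      strand <- if (g %% 2L == 1L) "+" else "-"
      biotype <- if (isRrna) "rRNA" else "protein_coding"
      if (isRrna) {
        u5 <- 0L; cdsLen <- 0L; u3 <- 0L
        exonic <- sample(100:160, 1L)
        k <- 1L
      } else {
        u5 <- randInt(1L, config$utr5Range)
        cdsLen <- 3L * randInt(1L, config$cdsCodons)
        u3 <- randInt(1L, config$utr3Range)
        exonic <- u5 + cdsLen + 3L + u3  # stop codon inside last exonic part
        k <- randInt(1L, config$exonsPerGene)
      }
      cuts <- if (k > 1L) sort(sample(seq_len(exonic - 1L), k - 1L)) else integer()
      exonWidths <- diff(c(0L, cuts, exonic))
      introns <- if (k > 1L) randInt(k - 1L, config$intronRange) else integer()
      exStarts <- integer(k); exEnds <- integer(k)
      pos <- cursor + sample(200:500, 1L)
      for (i in seq_len(k)) {
        exStarts[i] <- pos
        exEnds[i] <- pos + exonWidths[i] - 1L
        pos <- exEnds[i] + 1L + if (i < k) introns[i] else 0L
      }
      cursor <- pos
      exons <- IRanges(exStarts, exEnds)
      model <- new("TranscriptModel", transcriptId = tid, geneId = gid,
                   chrom = "chr1", strand = strand, biotype = biotype,
                   exons = exons, cds = IRanges(), canonical = !isRrna,
                   flags = character())
      map <- buildExonMap(model)
      attrsBase <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      geneAttr <- sprintf('gene_id "%s"; gene_biotype "%s";', gid, biotype)
      txAttr <- sprintf('%s transcript_biotype "%s";%s', attrsBase, biotype,
                        if (!isRrna) ' tag "Ensembl_canonical";' else "")
      addRec <- function(feature, ir, frame = ".", attrs = attrsBase) {
        lapply(seq_along(ir), function(i)
          data.frame(seqname = "chr1", source = "sim", feature = feature,
                     start = start(ir)[i], end = end(ir)[i], score = ".",
                     strand = strand,
                     frame = if (length(frame) > 1L) as.character(frame[i])
                             else frame,
                     attributes = attrs, stringsAsFactors = FALSE))
      }
      geneRec <- addRec("gene", IRanges(min(exStarts), max(exEnds)),
                        attrs = geneAttr)
      txRec <- addRec("transcript", IRanges(min(exStarts), max(exEnds)),
                      attrs = txAttr)
      exRec <- addRec("exon", exons, attrs = txAttr)
      cdsRec <- startRec <- stopRec <- u5Rec <- u3Rec <- list()
      if (!isRrna) {
        cds <- exonicRangeToGenomic(map, u5 + 1L, u5 + cdsLen)
        model@cds <- cds
        cdsRec <- addRec("CDS", cds, frame = cdsFrames(cds, strand),
                         attrs = txAttr)
        startIr <- exonicRangeToGenomic(map, u5 + 1L, u5 + 3L)
        stopIr <- exonicRangeToGenomic(map, u5 + cdsLen + 1L, u5 + cdsLen + 3L)
        startRec <- addRec("start_codon", startIr, frame = "0", attrs = txAttr)
        stopRec <- addRec("stop_codon", stopIr, frame = "0", attrs = txAttr)
        if (u5 > 0L)
          u5Rec <- addRec("five_prime_utr",
                          exonicRangeToGenomic(map, 1L, u5), attrs = txAttr)
        if (u3 > 0L)
          u3Rec <- addRec("three_prime_utr",
                          exonicRangeToGenomic(map, u5 + cdsLen + 4L, exonic),
                          attrs = txAttr)
        patches[[length(patches) + 1L]] <-
          list(pos = sort(exonicToGenomic(map, (u5 + 1L):(u5 + 3L))),
               codon = "ATG", strand = strand)
        patches[[length(patches) + 1L]] <-
          list(pos = sort(exonicToGenomic(map, (u5 + cdsLen + 1L):(u5 + cdsLen + 3L))),
               codon = "TAA", strand = strand)
      }
      recs[[g]] <- do.call(rbind, c(geneRec, txRec, exRec, cdsRec,
                                    startRec, stopRec, u5Rec, u3Rec))
      models[[tid]] <- model
      truth[[g]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = "chr1", strand = strand,
        biotype = biotype,
        exons = paste(sprintf("%d-%d", exStarts, exEnds), collapse = ";"),
        cds = if (isRrna) "" else
          paste(sprintf("%d-%d", start(model@cds), end(model@cds)),
                collapse = ";"),
        utr5_length = u5, cds_length = cdsLen, utr3_length = u3,
        exonic_length = exonic,
        expression = stats::rlnorm(1L, log(config$meanExpression), 0.5),
        stringsAsFactors = FALSE)
    }
    genomeLen <- cursor + 200L
    chars <- sample(c("A", "C", "G", "T"), genomeLen, replace = TRUE)
    for (p in patches) chars <- patchCodon(chars, p$pos, p$codon, p$strand)
    fastaPath <- file.path(dir, "genome.fa")
    genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
    names(genome) <- "chr1"
    Biostrings::writeXStringSet(genome, fastaPath)
    gtfPath <- file.path(dir, "annotation.gtf")
    rec <- do.call(rbind, recs)
    writeLines(c("#!genome-build sim1",
                 paste(rec$seqname, rec$source, rec$feature, rec$start,
                       rec$end, rec$score, rec$strand, rec$frame,
                       rec$attributes, sep = "\t")), gtfPath)
    truthDf <- do.call(rbind, truth)
    truthFile <- file.path(dir, "truth_transcripts.tsv")
    utils::write.table(truthDf, truthFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(fasta = fastaPath, gtf = gtfPath, truthFile = truthFile,
         truth = truthDf, models = models, genome = genome)
  })
}

# triangular pmf over the configured footprint lengths, peaked at the mode
footprintLengthPmf <- function(config) {
  ls <- config$footprintLengths
  w <- pmax(1 - abs(ls - config$footprintPeak) / (diff(range(ls)) + 1), 0.01)
  w / sum(w)
}

#' Simulate footprint or RNA reads against a synthetic reference
#'
#' Draws reads per gene proportional to the truth expression (times a TE
#' multiplier for the footprint assay), places footprints so that the true
#' P-site (5' end + \code{pSiteOffset}) sits in frame 0 within the CDS with
#' optional 5'/3' pile-up elevation, collapses duplicates/contaminants per
#' configuration, and writes a coordinate-sorted SAM (the ground-truth
#' alignments; no aligner is involved), a FASTQ, and a per-read truth TSV.
#' Contaminant rRNA-fragment reads appear in the FASTQ only.
#'
#' @param config \code{\link{simulationConfig}}.
#' @param reference result of \code{\link{simulateReference}}.
#' @param dir output directory.
#' @param sample sample label (file stem; also seeds this library's RNG
#'   stream together with \code{config$seed}).
#' @param assay \code{"rpf"} (footprints, CDS frame-0 placement) or
#'   \code{"rna"} (uniform placement over the transcript).
#' @param teMultipliers named per-gene TE multipliers (footprint assay
#'   only; default 1).
#' @return list: \code{sam}, \code{fastq}, \code{truthFile} paths and the
#'   per-read \code{truth} data.frame.
#' @export
simulateReads <- function(config, reference, dir, sample = "s1",
                          assay = c("rpf", "rna"), teMultipliers = NULL) {
  assay <- match.arg(assay)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sampleSeed <- sum(utf8ToInt(paste0(sample, assay))) %% 1000L
  withSimSeed(config$seed, 100L + sampleSeed, {
    truthTx <- reference$truth[reference$truth$biotype == "protein_coding", ]
    models <- reference$models
    genomeChars <- strsplit(as.character(reference$genome[[1L]]), "")[[1L]]
    w <- truthTx$expression
    if (assay == "rpf" && !is.null(teMultipliers))
      w <- w * teMultipliers[truthTx$gene_id]
    nPerGene <- stats::rmultinom(1L, config$readsPerSample, w / sum(w))[, 1L]
    pmf <- footprintLengthPmf(config)
    rows <- list()
    for (gi in seq_len(nrow(truthTx))) {
      n <- nPerGene[gi]
      if (n == 0L) next
      tx <- truthTx[gi, ]
      model <- models[[tx$transcript_id]]
      map <- buildExonMap(model)
      Tlen <- tx$exonic_length
      u5 <- tx$utr5_length
      cdsLen <- tx$cds_length
      lens <- sample(config$footprintLengths, n, replace = TRUE, prob = pmf)
      if (assay == "rpf") {
        nCod <- cdsLen %/% 3L
        codW <- rep(1, nCod)
        w5 <- min(ceiling(config$pileupWindow5 / 3), nCod)
        w3 <- min(ceiling(config$pileupWindow3 / 3), nCod)
        # initiation pile-up: strongest at the start codon, geometric decay
        # across the window (queued/paused ribosomes); mirror at termination
        codW[seq_len(w5)] <- 1 + (config$pileup5Factor - 1) *
          0.5^(seq_len(w5) - 1L)
        codW[nCod - seq_len(w3) + 1L] <- codW[nCod - seq_len(w3) + 1L] +
          (config$pileup3Factor - 1) * 0.5^(seq_len(w3) - 1L)
        five <- integer(n)
        for (i in seq_len(n)) {
          # codons whose footprint stays inside the transcript
          jMin <- max(1L, ceiling((config$pSiteOffset - u5) / 3) + 1L)
          jMax <- min(nCod,
                      (Tlen - lens[i] + config$pSiteOffset - u5 - 1L) %/% 3L + 1L)
          j <- sample(jMin:jMax, 1L, prob = codW[jMin:jMax])
          five[i] <- u5 + 3L * (j - 1L) + 1L - config$pSiteOffset
        }
      } else {
        five <- vapply(lens, function(l)
          sample.int(Tlen - l + 1L, 1L), 1L)
      }
      for (i in seq_len(n)) {
        blocks <- exonicRangeToGenomic(map, five[i], five[i] + lens[i] - 1L)
        cigar <- blocksToCigar(blocks)
        seqFwd <- paste(genomeChars[unlist(lapply(seq_along(blocks),
          function(b) start(blocks)[b]:end(blocks)[b]))], collapse = "")
        rows[[length(rows) + 1L]] <- data.frame(
          gene = tx$gene_id, transcript = tx$transcript_id,
          fivePrimeExonic = five[i], length = lens[i],
          chrom = tx$chrom, strand = tx$strand,
          pos = min(start(blocks)), cigar = cigar, seqFwd = seqFwd,
          stringsAsFactors = FALSE)
      }
    }
    reads <- do.call(rbind, rows)
    nUnique <- nrow(reads)
    reads$umi <- if (config$umis)
      vapply(seq_len(nUnique), function(i)
        paste(sample(c("A", "C", "G", "T"), 8L, replace = TRUE),
              collapse = ""), "") else NA_character_
    reads$duplicate <- FALSE
    reads$srcRead <- seq_len(nUnique)
    if (config$duplicationRate > 0) {
      nDup <- round(config$duplicationRate / (1 - config$duplicationRate) *
                      nUnique)
      if (nDup > 0L) {
        src <- sample.int(nUnique, nDup, replace = TRUE)
        dups <- reads[src, , drop = FALSE]
        dups$duplicate <- TRUE
        dups$srcRead <- src
        reads <- rbind(reads, dups)
      }
    }
    reads$readId <- sprintf("%s_r%06d%s", sample, seq_len(nrow(reads)),
                            ifelse(is.na(reads$umi), "",
                                   paste0("_", reads$umi)))
    # SAM, coordinate-sorted
    ord <- order(reads$chrom, reads$pos)
    samPath <- file.path(dir, paste0(sample, ".sam"))
    glen <- Biostrings::width(reference$genome)[1L]
    samLines <- c("@HD\tVN:1.6\tSO:coordinate",
                  paste0("@SQ\tSN:chr1\tLN:", glen),
                  sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                          reads$readId[ord],
                          ifelse(reads$strand[ord] == "-", 16L, 0L),
                          reads$chrom[ord], reads$pos[ord], 255L,
                          reads$cigar[ord], reads$seqFwd[ord],
                          strrep("I", reads$length[ord])))
    writeLines(samLines, samPath)
    # FASTQ: footprint sequences in read orientation, plus contaminants
    fqSeq <- ifelse(reads$strand == "-",
                    chartr("ACGT", "TGCA",
                           vapply(reads$seqFwd, function(s)
                             paste(rev(strsplit(s, "")[[1L]]), collapse = ""),
                             "")),
                    reads$seqFwd)
    fqIds <- reads$readId
    if (config$contaminationFraction > 0) {
      nCont <- round(config$contaminationFraction /
                       (1 - config$contaminationFraction) * nrow(reads))
      frag <- sample(config$rrnaFragments, nCont, replace = TRUE)
      fqSeq <- c(fqSeq, frag)
      fqIds <- c(fqIds, sprintf("%s_cont%06d", sample, seq_len(nCont)))
    }
    shuffle <- sample.int(length(fqSeq))
    fastqPath <- file.path(dir, paste0(sample, ".fastq"))
    writeLines(as.vector(rbind(paste0("@", fqIds[shuffle]),
                               fqSeq[shuffle],
                               "+",
                               strrep("I", nchar(fqSeq[shuffle])))),
               fastqPath)
    truthFile <- file.path(dir, paste0(sample, "_truth_reads.tsv"))
    utils::write.table(reads[, c("readId", "gene", "transcript",
                                 "fivePrimeExonic", "length", "chrom",
                                 "strand", "pos", "cigar", "duplicate",
                                 "srcRead")],
                       truthFile, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(sam = samPath, fastq = fastqPath, truthFile = truthFile,
         truth = reads)
  })
}

# ascending blocks -> CIGAR with N gaps
blocksToCigar <- function(blocks) {
  if (length(blocks) == 1L) return(paste0(width(blocks), "M"))
  parts <- character(0)
  for (i in seq_along(blocks)) {
    parts <- c(parts, paste0(width(blocks)[i], "M"))
    if (i < length(blocks))
      parts <- c(parts, paste0(start(blocks)[i + 1L] - end(blocks)[i] - 1L,
                               "N"))
  }
  paste(parts, collapse = "")
}

#' Simulate paired footprint/RNA count matrices with known TE structure
#'
#' Builds integer count matrices for a TE screen directly (no reads): gene
#' baselines are lognormal, the footprint counts of gene g in condition c
#' are scaled by the configured TE multiplier, and every entry receives
#' independent lognormal noise with the configured CV (0 = noise-free).
#'
#' @param config \code{\link{simulationConfig}} (uses seed, replicates,
#'   noiseCV, meanExpression).
#' @param nGenes number of genes.
#' @param teMultipliers genes x conditions numeric matrix of true TE
#'   multipliers (dimnames required).
#' @param lengths per-gene feature lengths (default 1000 nt each).
#' @return list: \code{rpf}, \code{rna} integer matrices; \code{conditions}
#'   named vector mapping samples to conditions; \code{lengths};
#'   \code{trueTE} the multiplier matrix.
#' @export
simulateTeCounts <- function(config, nGenes, teMultipliers, lengths = NULL) {
  stopifnot(nrow(teMultipliers) == nGenes)
  genes <- rownames(teMultipliers)
  conds <- colnames(teMultipliers)
  if (is.null(lengths))
    lengths <- structure(rep(1000L, nGenes), names = genes)
  withSimSeed(config$seed, 7L, {
    base <- stats::rlnorm(nGenes, log(config$meanExpression), 0.7)
    sdlog <- sqrt(log(1 + config$noiseCV^2))
    noise <- function(n) if (config$noiseCV == 0) rep(1, n)
                         else stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    cols <- list(rpf = list(), rna = list())
    conditions <- character(0)
    for (cond in conds) {
      for (r in seq_len(config$replicates)) {
        sn <- sprintf("%s_rep%d", cond, r)
        cols$rpf[[paste0("rpf_", sn)]] <-
          as.integer(round(base * teMultipliers[, cond] * noise(nGenes)))
        cols$rna[[paste0("rna_", sn)]] <-
          as.integer(round(base * noise(nGenes)))
        conditions[paste0("rpf_", sn)] <- cond
        conditions[paste0("rna_", sn)] <- cond
      }
    }
    rpf <- do.call(cbind, cols$rpf)
    rna <- do.call(cbind, cols$rna)
    rownames(rpf) <- rownames(rna) <- genes
    list(rpf = rpf, rna = rna, conditions = conditions,
         lengths = lengths, trueTE = teMultipliers)
  })
}
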