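test_that("the simulated reference is reproducible and respects its constraints", {
  cfg <- smallSimConfig()
  ref1 <- simulateReference(cfg)
  ref2 <- simulateReference(cfg)
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  expect_identical(ref1$exons, ref2$exons)

  expect_equal(length(unique(ref1$exons$gene_id)), 4L)
  expect_true(all(ref1$exons$end <= cfg@genomeLen))
  expect_true(all(ref1$exons$start >= 1L))
  # multi-exon genes on both strands
  nEx <- table(ref1$exons$gene_id)
  expect_true(all(nEx >= 2))
  expect_setequal(unique(ref1$exons$strand), c("+", "-"))
  # CDS lengths are multiples of 3
  for (tid in unique(ref1$cds$transcript_id)) {
    cds <- ref1$cds[ref1$cds$transcript_id == tid, ]
    expect_equal(sum(cds$end - cds$start + 1L) %% 3L, 0L)
  }
})

test_that("the paralog decoy carries the configured divergence", {
  cfg <- simConfig(seed = 3L, genomeLen = 20000L, nGenes = 4L,
                   nEditSites = 10L, paralogIdentity = 0.97,
                   paralogLen = 500L)
  ref <- simulateReference(cfg)
  pl <- ref$paralog
  expect_equal(pl$copy_end - pl$copy_start + 1L, 500L)
  # substitution count within 3 sigma of Binomial(500, 0.03)
  expect_lt(abs(pl$n_subst - 500 * 0.03), 3 * sqrt(500 * 0.03 * 0.97) + 1)
  src <- as.character(Biostrings::subseq(ref$genome[[1]], pl$src_start,
                                         pl$src_end))
  cp <- as.character(Biostrings::subseq(ref$genome[[1]], pl$copy_start,
                                        pl$copy_end))
  mism <- sum(strsplit(src, "")[[1]] != strsplit(cp, "")[[1]])
  expect_equal(mism, pl$n_subst)
})

test_that("planted truth is disjoint, ploidy-valid and on transcript strands", {
  run <- smallRun()
  truth <- run$sim$truth
  expect_equal(length(intersect(truth$snps$pos, truth$edits$pos)), 0L)
  expect_true(all(truth$edits$true_level >= 0.1 &
                    truth$edits$true_level <= 0.9))
  expect_true(all(ifelse(truth$edits$strand == "+",
                         truth$edits$ref == "A" & truth$edits$edited == "G",
                         truth$edits$ref == "T" & truth$edits$edited == "C")))
  expect_true(all(nchar(truth$snps$genotype) == 2L))
  expect_true(all(truth$snps$alt_copies == 1L))

  # higher ploidy draws valid allele splits
  cfg4 <- simConfig(seed = 2L, genomeLen = 20000L, nGenes = 4L,
                    nEditSites = 10L, ploidy = 4L, hetSnpRate = 0.002)
  ref4 <- simulateReference(cfg4)
  truth4 <- plantTruth(cfg4, ref4)
  expect_true(all(truth4$snps$alt_copies >= 1L &
                    truth4$snps$alt_copies <= 3L))
  expect_true(all(nchar(truth4$snps$genotype) == 4L))
})

test_that("SNP allele draws follow the planted genotype proportions", {
  cfg <- simConfig(seed = 8L, genomeLen = 20000L, nGenes = 4L,
                   nEditSites = 5L, ploidy = 4L, hetSnpRate = 0.003,
                   dnaDepth = 60)
  ref <- simulateReference(cfg)
  truth <- plantTruth(cfg, ref)
  reads <- simulateReads(cfg, ref, truth, "DNA")
  obs <- with(reads, {
    df <- data.frame(start = pos, end = pos + nchar(seq) - 1L, seq = seq)
    df
  })
  fracs <- vapply(seq_len(nrow(truth$snps)), function(j) {
    sp <- truth$snps$pos[j]
    idx <- which(obs$start <= sp & obs$end >= sp)
    b <- substr(obs$seq[idx], sp - obs$start[idx] + 1L,
                sp - obs$start[idx] + 1L)
    mean(b == truth$snps$alt[j])
  }, numeric(1))
  expected <- truth$snps$alt_copies / 4
  # each site's alt fraction within 3 sigma of its expectation (depth ~60)
  n <- 60
  tol <- 3 * sqrt(expected * (1 - expected) / n) + 0.05
  expect_true(all(abs(fracs - expected) < tol))
})

test_that("base errors track the quality profile", {
  cfg <- simConfig(seed = 4L, genomeLen = 20000L, nGenes = 4L,
                   nEditSites = 5L, hetSnpRate = 0, qualMean = 40,
                   qualSd = 0, dnaDepth = 30)
  ref <- simulateReference(cfg)
  truth <- plantTruth(cfg, ref)
  reads <- simulateReads(cfg, ref, truth, "DNA")
  gseq <- as.character(ref$genome[[1]])
  refStr <- substring(gseq, reads$pos, reads$pos + nchar(reads$seq) - 1L)
  mm <- sum(vapply(seq_len(nrow(reads)), function(i) {
    sum(strsplit(reads$seq[i], "")[[1]] != strsplit(refStr[i], "")[[1]])
  }, numeric(1)))
  nb <- sum(nchar(reads$seq))
  expect_lt(abs(mm - nb * 1e-4), 3 * sqrt(nb * 1e-4) + 3)
})

test_that("dUTP reads are antisense to their transcript and edits hit their level", {
  run <- smallRun()
  sim <- run$sim
  rna <- sim$rnaReads
  ref <- sim$ref
  # reads falling entirely inside one gene must oppose that gene's strand
  for (g in unique(ref$exons$gene_id)) {
    ex <- ref$exons[ref$exons$gene_id == g, ]
    inGene <- rna$pos >= min(ex$start) & rna$pos <= max(ex$end)
    if (!any(inGene)) next
    expect_true(all(rna$strand[inGene] != ex$strand[1]))
  }
  # a fully edited site is edited in (almost) all covering reads
  cfgFull <- simConfig(seed = 5L, genomeLen = 20000L, nGenes = 4L,
                       nEditSites = 5L, editLevelMin = 1, editLevelMax = 1,
                       hetSnpRate = 0)
  refF <- simulateReference(cfgFull)
  truthF <- plantTruth(cfgFull, refF)
  rnaF <- simulateReads(cfgFull, refF, truthF, "RNA")
  ends <- GenomicAlignments::cigarWidthAlongReferenceSpace(rnaF$cigar) +
    rnaF$pos - 1L
  for (j in seq_len(nrow(truthF$edits))) {
    sp <- truthF$edits$pos[j]
    idx <- which(rnaF$pos <= sp & ends >= sp)
    if (length(idx) < 5) next
    hit <- vapply(idx, function(i) {
      offs <- GenomicAlignments::cigarRangesAlongReferenceSpace(
        rnaF$cigar[i], pos = rnaF$pos[i])[[1]]
      qr <- GenomicAlignments::cigarRangesAlongQuerySpace(rnaF$cigar[i])[[1]]
      ops <- GenomicAlignments::explodeCigarOps(rnaF$cigar[i])[[1]]
      m <- ops %in% c("M", "=", "X")
      offs <- offs[m]; qr <- qr[m]
      blk <- which(IRanges::start(offs) <= sp & IRanges::end(offs) >= sp)
      if (!length(blk)) return(NA_character_)
      qp <- IRanges::start(qr[blk]) + sp - IRanges::start(offs[blk])
      substr(rnaF$seq[i], qp, qp)
    }, character(1))
    hit <- hit[!is.na(hit)]
    expect_gte(mean(hit == truthF$edits$edited[j]), 0.9)
  }
})

test_that("simulator outputs parse with standard readers", {
  run <- smallRun()
  paths <- run$sim$paths
  g <- Biostrings::readDNAStringSet(paths$genome)
  expect_equal(Biostrings::width(g), 20000L)
  gtf <- rtracklayer::import(paths$gtf)
  expect_true(all(c("exon", "CDS") %in% as.character(gtf$type)))
  reads <- readAlignments(paths$dnaSam)  # via Rsamtools::asBam + scanBam
  expect_gt(nrow(reads), 1000L)
  fq <- Biostrings::readDNAStringSet(paths$dnaFastq, format = "fastq")
  expect_equal(length(fq), nrow(run$sim$dnaReads))
  snps <- read.table(paths$snps, header = TRUE, sep = "\t")
  expect_true(all(c("chrom", "pos", "genotype") %in% names(snps)))
})

test_that("identical seeds reproduce identical fixture bytes", {
  d1 <- file.path(tempdir(), "editscan-det1")
  d2 <- file.path(tempdir(), "editscan-det2")
  cfg <- simConfig(seed = 99L, genomeLen = 12000L, nGenes = 2L,
                   nEditSites = 5L, dnaDepth = 8, rnaDepth = 10)
  simulateDataset(cfg, d1)
  simulateDataset(cfg, d2)
  for (f in c("genome.fa", "genes.gtf", "truth_snps.tsv", "truth_edits.tsv",
              "dna.sam", "rna.sam", "dna.fastq", "rna.fastq")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})
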