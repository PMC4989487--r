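mkFeatures <- function() {
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(101, 1201, 101, 1201, 2001, 2501),
                     c(700, 1800, 700, 1500, 2300, 2800)),
    strand = c("+", "+", "+", "+", "-", "-"),
    type = c("exon", "exon", "CDS", "CDS", "exon", "exon"),
    gene_id = c(rep("g1", 4), "g2", "g2"),
    transcript_id = c("t1", "t1", "t1", "t1", "t2", "t2"))
  buildFeatureIndex(gr)
}

test_that("site annotation reports all overlapping classes, or intergenic", {
  feats <- mkFeatures()
  cds <- annotateSite("chr1", 300, feats)
  expect_setequal(cds$feature_class, c("exon", "CDS"))
  expect_equal(unique(cds$gene_id), "g1")

  none <- annotateSite("chr1", 5000, feats)
  expect_equal(none$feature_class, "intergenic")

  # 3'-UTR of t1 (derived from exon minus CDS) plus intron of t2
  utr <- annotateSite("chr1", 1600, feats)
  expect_true("3'-UTR" %in% utr$feature_class)

  both <- annotateSite("chr1", 2400, feats)  # intron of t2
  expect_true("intron" %in% both$feature_class)
})

test_that("annotation is independent of feature input order", {
  feats <- mkFeatures()
  gr <- GenomicRanges::GRanges(
    "chr1",
    IRanges::IRanges(c(1201, 101, 1201, 101), c(1800, 700, 1500, 700)),
    strand = "+",
    type = c("exon", "exon", "CDS", "CDS"),
    gene_id = "g1", transcript_id = "t1")
  featsRev <- buildFeatureIndex(gr)
  a <- annotateSite("chr1", 300, feats)
  b <- annotateSite("chr1", 300, featsRev)
  expect_equal(a$feature_class, b$feature_class)
})

test_that("codon changes follow the genetic code on both strands", {
  # plus strand: CDS 1..9, codon 2 = AAG; A->G at its 2nd base gives AGG
  g <- Biostrings::DNAStringSet(c(chr1 = "ATGAAGGCATAAACGTACGT"))
  gr <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1), c(12, 12)), strand = "+",
    type = c("exon", "CDS"), gene_id = "g", transcript_id = "t")
  feats <- buildFeatureIndex(gr)
  cc <- codonChange("chr1", 5, "G", "t", feats, g)
  expect_equal(cc$codon_before, "AAG")
  expect_equal(cc$codon_after, "AGG")
  expect_equal(cc$aa_before, "K")
  expect_equal(cc$aa_after, "R")
  expect_false(cc$synonymous)
  expect_equal(cc$codon_position, 2L)

  # wobble position: GCA -> GCG is synonymous (A -> A)
  cc3 <- codonChange("chr1", 9, "G", "t", feats, g)
  expect_equal(cc3$codon_before, "GCA")
  expect_equal(cc3$codon_after, "GCG")
  expect_true(cc3$synonymous)

  # minus strand: genomic T->C is A->G on the transcript
  gm <- Biostrings::DNAStringSet(c(chr1 = "GGTTACTTCATGGTACGTAC"))
  # transcript (revcomp of 1..12): CCATGAAGTAAC -> CDS on - strand 1..12
  grm <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1), c(12, 12)), strand = "-",
    type = c("exon", "CDS"), gene_id = "g", transcript_id = "t")
  featsM <- buildFeatureIndex(grm)
  # genomic pos 8 is T; on the transcript it is codon base A
  ccm <- codonChange("chr1", 8, "C", "t", featsM, gm)
  expect_equal(nchar(ccm$codon_before), 3L)
  expect_equal(ccm$aa_before,
               unname(Biostrings::GENETIC_CODE[ccm$codon_before]))
  expect_true(grepl("G", ccm$codon_after))
  expect_false(identical(ccm$codon_before, ccm$codon_after))

  # non-multiple-of-3 CDS warns and yields no codon change
  grBad <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1), c(11, 11)), strand = "+",
    type = c("exon", "CDS"), gene_id = "g", transcript_id = "t")
  featsBad <- buildFeatureIndex(grBad)
  expect_warning(out <- codonChange("chr1", 5, "G", "t", featsBad, g),
                 "multiple of 3")
  expect_null(out)
})

test_that("codon assembly round-trips through spliced translation", {
  run <- smallRun()
  ref <- run$sim$ref
  genome <- ref$genome
  for (tid in unique(ref$cds$transcript_id)) {
    cds <- ref$cds[ref$cds$transcript_id == tid, , drop = FALSE]
    cds <- cds[order(cds$start), , drop = FALSE]
    sq <- paste(vapply(seq_len(nrow(cds)), function(i) {
      as.character(Biostrings::subseq(genome[[cds$chrom[i]]],
                                      cds$start[i], cds$end[i]))
    }, character(1)), collapse = "")
    if (cds$strand[1] == "-") sq <- revComp(sq)
    expect_equal(nchar(sq) %% 3, 0)
    direct <- as.character(Biostrings::translate(Biostrings::DNAString(sq)))
    codons <- substring(sq, seq(1, nchar(sq), 3), seq(3, nchar(sq), 3))
    viaCodons <- paste(Biostrings::GENETIC_CODE[codons], collapse = "")
    expect_equal(viaCodons, direct)
  }
})

test_that("the pipeline annotates passing sites with features and codons", {
  run <- smallRun()
  tab <- run$res$table
  expect_true("feature_classes" %in% names(tab))
  pass <- tab[tab$pass, ]
  expect_true(all(nzchar(pass$feature_classes)))
  expect_true(all(grepl("exon", pass$feature_classes)))
  inCds <- grepl("CDS", pass$feature_classes)
  if (any(inCds)) {
    expect_true(all(nchar(pass$codon_before[inCds]) == 3L))
    expect_true(all(pass$synonymous[inCds] ==
                      (pass$aa_before[inCds] == pass$aa_after[inCds])))
  }
})
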