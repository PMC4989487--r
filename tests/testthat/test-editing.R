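test_that("candidate detection enforces support, level and non-redundancy", {
  g <- toyGenome()
  refb <- as.character(Biostrings::subseq(g[[1]], 500, 500))
  alt <- setdiff(c("A", "C", "G", "T"), refb)[1]
  cfg <- filterConfig()

  # n = 20, k = 1: level exactly 5% passes the level check, support fails
  obs <- obsRows(c(rep(refb, 19), alt), read_start = 400L + 1:20)
  cand <- detectCandidates(obs, g, cfg, emitAll = TRUE)
  expect_equal(cand$n_total, 20L)
  expect_equal(cand$k_edited, 1L)
  expect_equal(cand$editing_level, 0.05)
  expect_true(cand$level)
  expect_false(cand$support)
  # default emission drops it
  expect_equal(nrow(detectCandidates(obs, g, cfg)), 0L)

  # three supporting reads with identical footprints collapse to one
  dup <- obsRows(rep(alt, 3), read_start = 450L, read_end = 539L)
  candDup <- detectCandidates(dup, g, cfg, emitAll = TRUE)
  expect_equal(candDup$k_edited, 1L)
  expect_false(candDup$support)

  # two distinct alternative bases flag the multi-type verdict
  alts2 <- setdiff(c("A", "C", "G", "T"), refb)[1:2]
  multi <- obsRows(c(rep(alts2[1], 3), rep(alts2[2], 2)),
                   read_start = 400L + 1:5)
  candM <- detectCandidates(multi, g, cfg, emitAll = TRUE)
  expect_false(candM$multi_type)
  expect_equal(candM$n_alt_types, 2L)
  expect_equal(candM$alt_base, alts2[1])
})

test_that("editing types are reported on the transcript strand", {
  expect_equal(inferEditType("A", "G", "+"), "A-to-G")
  expect_equal(inferEditType("T", "C", "-"), "A-to-G")
  expect_equal(inferEditType("C", "T", "."), "C-to-T")
  expect_error(inferEditType("A", "A", "+"), "differ")

  # dUTP single-end reads are antisense to the transcript
  so <- obsRows(rep("G", 4), read_strand = "-")
  expect_equal(inferTranscriptStrand(so, "stranded_dUTP"), "+")
  so2 <- obsRows(rep("C", 4), read_strand = "+")
  expect_equal(inferTranscriptStrand(so2, "stranded_dUTP"), "-")
  # second-in-pair orientation equals the transcript strand
  so3 <- obsRows(rep("G", 4), read_strand = "+", mate = "second")
  expect_equal(inferTranscriptStrand(so3, "stranded_dUTP"), "+")
  # unstranded: unique overlapping gene, else "."
  expect_equal(inferTranscriptStrand(so, "unstranded", geneStrand = "-"),
               "-")
  expect_equal(inferTranscriptStrand(so, "unstranded",
                                     geneStrand = c("+", "-")), ".")
})

test_that("mid-read window is the central half fixed by the 90-bp example", {
  expect_equal(midReadWindow(90), c(23L, 68L))
  expect_equal(midReadWindow(4), c(2L, 3L))
  expect_equal(midReadWindow(100), c(26L, 75L))
  expect_error(midReadWindow(3), ">= 4")
})

test_that("splice-distance filter discards only near-splice intronic sites", {
  feats <- buildFeatureIndex(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 1201), c(700, 1800)), strand = "+",
    type = "exon", gene_id = "g1", transcript_id = "t1"))
  # intron is 701..1200; first intronic base is distance 1 from the donor
  expect_false(spliceDistanceFilter("chr1", 706, feats, 6L))  # distance 6
  expect_true(spliceDistanceFilter("chr1", 707, feats, 6L))   # distance 7
  expect_false(spliceDistanceFilter("chr1", 1196, feats, 6L)) # acceptor side
  expect_true(spliceDistanceFilter("chr1", 700, feats, 6L))   # exonic
  expect_true(spliceDistanceFilter("chr1", 1201, feats, 6L))  # exonic
  expect_true(spliceDistanceFilter("chr1", 5000, feats, 6L))  # intergenic
})

test_that("homopolymer filter discards runs at or above the threshold", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTAAAAACGTTTTACGGGGGGC"))
  expect_false(homopolymerFilter(g, "chr1", 7, 5L))   # inside AAAAA
  expect_false(homopolymerFilter(g, "chr1", 5, 5L))   # first base of the run
  expect_true(homopolymerFilter(g, "chr1", 13, 5L))   # TTTT, run of 4
  expect_false(homopolymerFilter(g, "chr1", 18, 5L))  # first base of GGGGGG
  expect_true(homopolymerFilter(g, "chr1", 2, 5L))
})

test_that("DNA depth cap is inclusive at the boundary", {
  expect_false(depthCapFilter(61, 30, 2))
  expect_true(depthCapFilter(60, 30, 2))
  expect_true(depthCapFilter(10, 30, 2))
})

test_that("binomial error test matches closed forms and the exact-sum oracle", {
  expect_equal(binomErrorTest(0, 10, 0.001), 1)
  expect_equal(binomErrorTest(3, 3, 0.001), 1e-9)
  expect_equal(binomErrorTest(2, 100, 0.001),
               1 - 0.999^100 - 100 * 0.001 * 0.999^99, tolerance = 1e-12)
  for (n in c(1, 5, 12, 30)) {
    for (k in 0:n) {
      expect_equal(binomErrorTest(k, n, 0.01),
                   oracleBinomTail(k, n, 0.01), tolerance = 1e-10)
    }
  }
  expect_error(binomErrorTest(5, 3, 0.001), "exceed")
})

test_that("BH q-values match hand computations and the brute-force oracle", {
  expect_equal(bhFdr(0.2), 0.2)
  expect_equal(bhFdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhFdr(c(0.5, 0.001)), c(0.5, 0.002))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhFdr(p), oracleBH(p), tolerance = 1e-12)
  }
})

test_that("the cascade verdict set is independent of candidate order", {
  run <- smallRun()
  res <- run$res
  cand <- detectCandidates(res$rnaObs, res$genome, res$cfg)
  ctx <- list(genome = res$genome, dnaObs = res$dnaObs,
              features = res$features, knownSnps = NULL,
              meanDnaDepth = res$meanDnaDepth, reads = res$rnaReads,
              cfg = res$cfg)
  fwd <- applyFilterCascade(cand, ctx)
  rev <- applyFilterCascade(cand[rev(seq_len(nrow(cand))), ], ctx)
  rev <- rev[order(rev$chrom, rev$pos), ]
  fwd <- fwd[order(fwd$chrom, fwd$pos), ]
  expect_equal(fwd$pass, rev$pass)
  expect_equal(fwd$q_value, rev$q_value)
})

test_that("the cascade errors when context is incomplete", {
  run <- smallRun()
  res <- run$res
  cand <- detectCandidates(res$rnaObs, res$genome, res$cfg)
  expect_error(applyFilterCascade(cand, list(genome = res$genome,
                                             cfg = res$cfg)),
               "dnaObs")
})

test_that("known-SNP exclusion removes supplied positions", {
  run <- smallRun()
  res <- run$res
  cand <- detectCandidates(res$rnaObs, res$genome, res$cfg)
  snp <- data.frame(chrom = cand$chrom[1], pos = cand$pos[1])
  ctx <- list(genome = res$genome, dnaObs = res$dnaObs,
              features = res$features, knownSnps = snp,
              meanDnaDepth = res$meanDnaDepth, reads = res$rnaReads,
              cfg = res$cfg)
  out <- applyFilterCascade(cand, ctx)
  expect_false(out$known_snp_excluded[1])
  expect_false(out$pass[1])
  expect_true(all(out$known_snp_excluded[-1]))
})
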