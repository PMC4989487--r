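# Scenario builder for filter-isolation tests: a hand-constructed candidate
# site whose observation stacks, DNA evidence and genome context satisfy
# every cascade filter, with hooks to perturb exactly one aspect.

cascadeScenario <- function(pos = 500L,
                            nRef = 34L, kAlt = 6L,
                            extraAltCount = 0L,
                            dnaRef = 30L, dnaAlt = 0L,
                            meanDnaDepth = 30,
                            readPos = NULL,
                            genome = NULL,
                            knownSnps = NULL,
                            cfg = filterConfig(),
                            plantHomopolymer = FALSE,
                            plantParalog = FALSE) {
  if (is.null(genome)) {
    g <- as.character(toyGenome()[[1]])
    if (plantHomopolymer) {
      b <- substr(g, pos, pos)
      substr(g, pos - 2L, pos + 2L) <- strrep(b, 5L)
    }
    if (plantParalog) {
      # append a copy of the read-bearing region with a single difference
      src <- substr(g, pos - 150L, pos + 150L)
      diffAt <- 30L
      substr(src, diffAt, diffAt) <-
        setdiff(c("A", "C", "G", "T"), substr(src, diffAt, diffAt))[1]
      g <- paste0(g, src)
    }
    genome <- Biostrings::DNAStringSet(c(chr1 = g))
  }
  gseq <- as.character(genome[[1]])
  ref <- substr(gseq, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]

  n <- nRef + kAlt + extraAltCount
  ## distinct footprints that all cover pos at an unclipped cycle: cycle
  ## offsets 23..76 repeat, with the read end stretched per repeat block;
  ## supporting (alt) reads come first so they sit inside the mid window
  i <- seq_len(n) - 1L
  starts <- pos - 22L - (i %% 54L)
  ends <- starts + 89L + (i %/% 54L)
  if (is.null(readPos)) readPos <- pos - starts + 1L
  thirdBase <- setdiff(c("A", "C", "G", "T"), c(ref, alt))[1]
  bases <- c(rep(alt, kAlt), rep(ref, nRef), rep(thirdBase, extraAltCount))
  rna <- data.frame(chrom = "chr1", pos = pos, base = bases, qual = 35L,
                    rid = seq_len(n), read_pos = rep_len(readPos, n),
                    read_len = ends - starts + 1L, read_start = starts,
                    read_end = ends, read_strand = "+",
                    mate = "single", seg_qstart = 1L,
                    seg_qend = ends - starts + 1L,
                    stringsAsFactors = FALSE)
  dna <- obsRows(c(rep(ref, dnaRef), rep(alt, dnaAlt)), qual = 40L,
                 pos = pos, read_start = pos - 60L + seq_len(dnaRef + dnaAlt))

  # read sequences consistent with the footprints, carrying the edit
  seqs <- substring(gseq, starts, ends)
  for (i in seq_len(n)) {
    substr(seqs[i], pos - starts[i] + 1L, pos - starts[i] + 1L) <- bases[i]
  }
  reads <- data.frame(rid = seq_len(n), seq = seqs, stringsAsFactors = FALSE)

  features <- buildFeatureIndex(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(101, 1201), c(700, 1800)), strand = "+",
    type = "exon", gene_id = "g1", transcript_id = "t1"))

  cand <- detectCandidates(rna, genome, cfg, emitAll = TRUE)
  ctx <- list(genome = genome, dnaObs = dna, features = features,
              knownSnps = knownSnps, meanDnaDepth = meanDnaDepth,
              reads = reads, cfg = cfg)
  applyFilterCascade(cand, ctx)
}


# Assert that exactly `filter` fails (other verdicts are TRUE or undefined).
expectOnlyFails <- function(out, filter) {
  testthat::expect_equal(nrow(out), 1L)
  for (f in editscan:::CASCADE_FILTERS) {
    val <- out[[f]][1]
    if (f == filter) {
      testthat::expect_false(isTRUE(val), label = paste(f, "should fail"))
      testthat::expect_false(is.na(val), label = paste(f, "is defined"))
    } else {
      testthat::expect_true(isTRUE(val) || is.na(val),
                            label = paste(f, "should not fail"))
    }
  }
  testthat::expect_false(out$pass[1])
}
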