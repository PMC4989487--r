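# Shared fixtures. Expensive simulations are built once per test run and
# memoized here; everything is generated in code under fixed seeds.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]])) .fixtureCache[[name]] <- builder()
  .fixtureCache[[name]]
}

# A tiny deterministic genome for unit tests.
toyGenome <- function(len = 4000L, seed = 42L) {
  set.seed(seed)
  g <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""))
  names(g) <- "chr1"
  g
}

# A two-exon toy gene on the toy genome.
toyExons <- function() {
  data.frame(chrom = "chr1", start = c(101L, 1201L), end = c(700L, 1800L),
             strand = "+", transcript_id = "t1", gene_id = "g1",
             stringsAsFactors = FALSE)
}

# Hand-built observation rows with explicit footprints.
obsRows <- function(base, qual = 35L, read_start = 1L, read_end = 90L,
                    read_strand = "+", mate = "single", read_pos = 45L,
                    read_len = 90L, chrom = "chr1", pos = 500L,
                    rid = seq_along(base), seg_qstart = 1L,
                    seg_qend = 90L) {
  data.frame(chrom = chrom, pos = pos, base = base,
             qual = rep_len(qual, length(base)), rid = rid,
             read_pos = rep_len(read_pos, length(base)),
             read_len = rep_len(read_len, length(base)),
             read_start = rep_len(read_start, length(base)),
             read_end = rep_len(read_end, length(base)),
             read_strand = rep_len(read_strand, length(base)),
             mate = rep_len(mate, length(base)),
             seg_qstart = rep_len(seg_qstart, length(base)),
             seg_qend = rep_len(seg_qend, length(base)),
             stringsAsFactors = FALSE)
}

# The standard validation fixture at the default simulation regime,
# run through the full single-sample pipeline.
standardRun <- function() {
  cachedFixture("standardRun", function() {
    dir <- file.path(tempdir(), "editscan-std")
    sim <- simulateDataset(simConfig(seed = 20260929L), dir)
    sr <- sampleRun("std", sim$paths$dnaSam, sim$paths$rnaSam,
                    sim$paths$genome, geneModels = sim$paths$gtf)
    res <- suppressMessages(runSingleSample(sr))
    list(sim = sim, res = res)
  })
}

# A small fixture shared by multi-sample and annotation tests.
smallSimConfig <- function(seed = 7L) {
  simConfig(seed = seed, genomeLen = 20000L, nGenes = 4L, nEditSites = 15L,
            dnaDepth = 25, rnaDepth = 40)
}

smallRun <- function() {
  cachedFixture("smallRun", function() {
    dir <- file.path(tempdir(), "editscan-small")
    sim <- simulateDataset(smallSimConfig(), dir)
    sr <- sampleRun("small", sim$paths$dnaSam, sim$paths$rnaSam,
                    sim$paths$genome, geneModels = sim$paths$gtf)
    res <- suppressMessages(runSingleSample(sr))
    list(sim = sim, res = res)
  })
}

# Two-sample fixture: shared genome and truth, sample-specific reads; the
# second sample expresses every planted edit at a very low level so that
# discovery misses most of them and liberal retrieval recovers them.
twoSampleFixture <- function() {
  cachedFixture("twoSample", function() {
    cfg <- smallSimConfig(seed = 11L)
    ref <- simulateReference(cfg)
    truth <- plantTruth(cfg, ref)
    truthLow <- truth
    truthLow$edits$true_level <- 0.03

    dirA <- file.path(tempdir(), "editscan-msA")
    dirB <- file.path(tempdir(), "editscan-msB")
    simA <- simulateDataset(cfg, dirA, truth = truth, readSeed = 101L)
    simB <- simulateDataset(cfg, dirB, truth = truthLow, readSeed = 202L)
    srA <- sampleRun("A", simA$paths$dnaSam, simA$paths$rnaSam,
                     simA$paths$genome, geneModels = simA$paths$gtf)
    srB <- sampleRun("B", simB$paths$dnaSam, simB$paths$rnaSam,
                     simB$paths$genome, geneModels = simB$paths$gtf)
    ms <- suppressMessages(runMultiSample(list(srA, srB)))
    list(cfg = cfg, truth = truth, truthLow = truthLow, ms = ms)
  })
}

# Independent oracle: exact binomial upper tail by explicit summation.
oracleBinomTail <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) choose(n, j) * p^j * (1 - p)^(n - j),
             numeric(1)))
}

# Independent oracle: brute-force BH step-up.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Independent oracle: genotype space by brute-force multiset enumeration,
# restricted to at most two distinct alleles.
oracleGenotypeSpace <- function(p) {
  combos <- do.call(expand.grid,
                    rep(list(c("A", "C", "G", "T")), p))
  gs <- unique(apply(combos, 1, function(a) paste(sort(a), collapse = "")))
  gs[vapply(strsplit(gs, ""), function(a) length(unique(a)) <= 2,
            logical(1))]
}
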