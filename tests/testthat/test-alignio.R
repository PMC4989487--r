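samRow <- function(qname, pos, seq, flag = 0L, mapq = 37L,
                   cigar = sprintf("%dM", nchar(seq)),
                   qual = strrep("I", nchar(seq)), chrom = "chr1") {
  data.frame(qname = qname, flag = flag, chrom = chrom, pos = pos,
             mapq = mapq, cigar = cigar, seq = seq, qual = qual,
             strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
             stringsAsFactors = FALSE)
}

writeToySam <- function(rows, genome = toyGenome()) {
  path <- tempfile(fileext = ".sam")
  writeSam(do.call(rbind, rows), genome, path)
  path
}

test_that("SAM round-trips through the reader with all fields intact", {
  g <- toyGenome()
  sq <- as.character(Biostrings::subseq(g[[1]], 101, 190))
  path <- writeToySam(list(samRow("r1", 101L, sq),
                           samRow("r2", 151L, sq, flag = 16L)))
  reads <- readAlignments(path)
  expect_equal(nrow(reads), 2L)
  r1 <- reads[reads$qname == "r1", ]
  expect_equal(r1$start, 101L)
  expect_equal(r1$end, 190L)
  expect_equal(r1$strand, "+")
  expect_equal(r1$seq, sq)
  expect_equal(r1$x0, 1L)
  expect_equal(r1$x1, 0L)
  expect_equal(reads$strand[reads$qname == "r2"], "-")
})

test_that("duplicate removal keeps the highest-mapq read and is order-independent", {
  g <- toyGenome()
  sq <- as.character(Biostrings::subseq(g[[1]], 101, 190))
  rows <- list(samRow("dupA", 101L, sq, mapq = 37L),
               samRow("dupB", 101L, sq, mapq = 20L),
               samRow("solo", 301L, sq))
  kept1 <- filterReads(readAlignments(writeToySam(rows)))
  expect_equal(sort(kept1$qname), c("dupA", "solo"))
  kept2 <- filterReads(readAlignments(writeToySam(rows[c(3, 2, 1)])))
  expect_equal(sort(kept2$qname), sort(kept1$qname))
  # idempotent
  expect_equal(nrow(filterReads(kept1)), nrow(kept1))
})

test_that("reads with suboptimal hits are dropped; tag-free input falls back to mapq", {
  g <- toyGenome()
  sq <- as.character(Biostrings::subseq(g[[1]], 101, 190))
  path <- tempfile(fileext = ".sam")
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:chr1\tLN:%d", Biostrings::width(g)),
             sprintf("multi\t0\tchr1\t101\t37\t90M\t*\t0\t0\t%s\t%s\tX0:i:1\tX1:i:1",
                     sq, strrep("I", 90)),
             sprintf("uniq\t0\tchr1\t201\t37\t90M\t*\t0\t0\t%s\t%s\tX0:i:1\tX1:i:0",
                     sq, strrep("I", 90)))
  writeLines(lines, path)
  kept <- filterReads(readAlignments(path))
  expect_equal(kept$qname, "uniq")

  # no tags at all: mapq floor applies, with a notice
  lines2 <- c(lines[1:2],
              sprintf("low\t0\tchr1\t101\t5\t90M\t*\t0\t0\t%s\t%s", sq,
                      strrep("I", 90)),
              sprintf("high\t0\tchr1\t201\t37\t90M\t*\t0\t0\t%s\t%s", sq,
                      strrep("I", 90)))
  path2 <- tempfile(fileext = ".sam")
  writeLines(lines2, path2)
  expect_message(kept2 <- filterReads(readAlignments(path2)), "mapq")
  expect_equal(kept2$qname, "high")
})

test_that("pileup honors clipping, quality threshold and N exclusion", {
  g <- toyGenome()
  sq <- as.character(Biostrings::subseq(g[[1]], 101, 190))
  reads <- readAlignments(writeToySam(list(samRow("r1", 101L, sq))))
  obs <- pileupObservations(reads, g, minBaseQual = 0L, clipN = 6L)
  # a 90-bp read clipped 6+6 leaves 78 usable positions
  expect_equal(nrow(obs), 78L)
  expect_equal(range(obs$pos), c(107L, 184L))
  expect_true(all(obs$read_pos > 6L & obs$read_pos <= 84L))
  # pileup bases agree with the reference they were drawn from
  expect_equal(obs$base,
               strsplit(sq, "")[[1]][obs$read_pos])

  # quality gate: one low-quality base among three reads
  qual <- paste0(strrep("I", 44), "#", strrep("I", 45))  # Q2 at cycle 45
  rows <- list(samRow("a", 101L, sq), samRow("b", 101L, sq),
               samRow("c", 101L, sq, qual = qual))
  reads3 <- readAlignments(writeToySam(rows))
  obs3 <- pileupObservations(reads3, g, minBaseQual = 30L, clipN = 6L)
  expect_equal(sum(obs3$pos == 145L), 2L)

  # N bases never appear
  sqN <- paste0(substr(sq, 1, 44), "N", substr(sq, 46, 90))
  readsN <- readAlignments(writeToySam(list(samRow("n", 101L, sqN))))
  obsN <- pileupObservations(readsN, g, minBaseQual = 0L, clipN = 6L)
  expect_false(any(obsN$base == "N"))
  expect_equal(sum(obsN$pos == 145L), 0L)
})

test_that("spliced alignments contribute no observations inside the intron", {
  g <- toyGenome()
  left <- as.character(Biostrings::subseq(g[[1]], 656, 700))
  right <- as.character(Biostrings::subseq(g[[1]], 1201, 1245))
  reads <- readAlignments(writeToySam(list(
    samRow("spl", 656L, paste0(left, right), cigar = "45M500N45M"))))
  obs <- pileupObservations(reads, g, minBaseQual = 0L, clipN = 0L)
  expect_equal(nrow(obs), 90L)
  expect_setequal(obs$pos, c(656:700, 1201:1245))
  # block-local query ranges are tracked for realignment
  expect_equal(unique(obs$seg_qstart[obs$pos <= 700]), 1L)
  expect_equal(unique(obs$seg_qstart[obs$pos >= 1201]), 46L)
})

test_that("pileup depth never exceeds retained coverage and errors name missing chroms", {
  g <- toyGenome()
  sq <- as.character(Biostrings::subseq(g[[1]], 101, 190))
  rows <- lapply(1:3, function(i)
    samRow(paste0("r", i), 101L + i, substr(sq, 1 + i, 90)))
  reads <- filterReads(readAlignments(writeToySam(rows)))
  obs <- pileupObservations(reads, g, minBaseQual = 0L, clipN = 6L)
  expect_lte(max(table(obs$pos)), nrow(reads))

  bad <- readAlignments(writeToySam(list(samRow("r1", 101L, sq))))
  bad$chrom <- "chrMissing"
  expect_error(pileupObservations(bad, g), "chrMissing")
})
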