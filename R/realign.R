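## Independent realignment of editing-supporting reads.
##
## Reads that support editing carry a mismatch to the reference, exactly the
## situation in which a mapper may have placed a read from a paralogous copy.
## Every supporting read is therefore realigned from scratch with an exact
## k-mer seeded, ungapped-extension local aligner whose score is the number
## of matching bases (a match-count score in the style of BLAT). A read
## qualifies when its best hit covers the candidate site and any second-best
## hit scores below 95% of the best; a candidate survives only when the
## fraction of qualifying reads exceeds 50%.

#' Realign a read against the genome
#'
#' Exact \code{seedLen}-mers sampled along the read (both orientations) seed
#' candidate loci, each of which is scored by ungapped comparison of the
#' full read against the reference; the score is the number of matching
#' bases. Hits scoring below \code{minScoreFrac} of the read length are
#' dropped.
#'
#' @param seq Read sequence (character).
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @param seedLen Seed k-mer length (default 11).
#' @param minScoreFrac Score floor as a fraction of read length (default 0.5).
#' @return A data.frame of hits sorted by decreasing score: \code{chrom},
#'   \code{start}, \code{end}, \code{strand}, \code{score}, \code{rank}.
#' @export
realignRead <- function(seq, genome, seedLen = 11L, minScoreFrac = 0.5) {
  genome <- loadGenome(genome)
  L <- nchar(seq)
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = integer(), rank = integer(),
                      stringsAsFactors = FALSE)
  if (L < seedLen) return(empty)
  queries <- c("+" = seq, "-" = revComp(seq))
  seedStarts <- unique(c(seq(1L, L - seedLen + 1L, by = seedLen),
                         L - seedLen + 1L))
  hits <- list()
  for (std in names(queries)) {
    q <- queries[[std]]
    loci <- list()
    for (ss in seedStarts) {
      kmer <- substr(q, ss, ss + seedLen - 1L)
      if (grepl("N", kmer, fixed = TRUE)) next
      for (ch in names(genome)) {
        m <- Biostrings::matchPattern(kmer, genome[[ch]])
        if (length(m))
          loci[[length(loci) + 1L]] <- data.frame(
            chrom = ch, aln_start = IRanges::start(m) - (ss - 1L),
            stringsAsFactors = FALSE)
      }
    }
    if (!length(loci)) next
    loci <- unique(do.call(rbind, loci))
    qv <- strsplit(q, "")[[1]]
    for (i in seq_len(nrow(loci))) {
      ch <- loci$chrom[i]; a <- loci$aln_start[i]
      gl <- length(genome[[ch]])
      lo <- max(1L, a); hi <- min(gl, a + L - 1L)
      if (hi < lo) next
      ref <- strsplit(as.character(
        Biostrings::subseq(genome[[ch]], lo, hi)), "")[[1]]
      qpart <- qv[(lo - a + 1L):(hi - a + 1L)]
      score <- sum(qpart == ref)
      if (score >= minScoreFrac * L)
        hits[[length(hits) + 1L]] <- data.frame(
          chrom = ch, start = lo, end = hi, strand = std,
          score = as.integer(score), stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  h <- h[!duplicated(paste(h$chrom, h$start, h$end, h$strand)), ,
         drop = FALSE]
  h <- h[order(-h$score, h$chrom, h$start, h$strand), , drop = FALSE]
  h$rank <- seq_len(nrow(h))
  rownames(h) <- NULL
  h
}

#' Realign the supporting reads of a candidate
#'
#' @param seqs Named character vector of supporting-read sequences (names are
#'   read ids); for spliced reads, pass the aligned block containing the
#'   candidate site.
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @param seedLen,minScoreFrac Aligner parameters (see
#'   \code{\link{realignRead}}).
#' @return Named list of hit data.frames, one per read.
#' @export
realignSupportingReads <- function(seqs, genome, seedLen = 11L,
                                   minScoreFrac = 0.5) {
  genome <- loadGenome(genome)
  lapply(stats::setNames(as.list(seqs), names(seqs)), realignRead,
         genome = genome, seedLen = seedLen, minScoreFrac = minScoreFrac)
}

#' Qualifying-read fraction of a candidate
#'
#' A realigned read qualifies when (1) its best hit's span contains the
#' candidate position and (2) its second-best hit, if any, scores strictly
#' below \code{secondRatio} times the best score. The candidate passes when
#' the qualifying fraction strictly exceeds \code{minFraction}; with zero
#' realigned reads the fraction is 0 and the candidate fails.
#'
#' @param chrom,pos Candidate site coordinates.
#' @param realignments List of hit data.frames from
#'   \code{\link{realignSupportingReads}}.
#' @param secondRatio Second-best/best score ceiling (default 0.95).
#' @param minFraction Qualifying fraction that must be exceeded (default 0.5).
#' @return A list: \code{fraction} and \code{pass}.
#' @export
qualifyingFraction <- function(chrom, pos, realignments,
                               secondRatio = 0.95, minFraction = 0.50) {
  if (!length(realignments)) return(list(fraction = 0, pass = FALSE))
  qual <- vapply(realignments, function(h) {
    if (!nrow(h)) return(FALSE)  # unevaluable read: conservative fail
    best <- h[1, ]
    overlaps <- best$chrom == chrom && best$start <= pos && best$end >= pos
    noRival <- nrow(h) < 2L || h$score[2] < secondRatio * h$score[1]
    overlaps && noRival
  }, logical(1))
  frac <- mean(qual)
  list(fraction = frac, pass = frac > minFraction)
}

## Cascade hook: realign the supporting reads of every candidate. Spliced
## supporting reads contribute the aligned block that contains the site
## (seg_qstart/seg_qend from the pileup); reads whose sequence cannot be
## recovered make the candidate unevaluable, which fails conservatively.
realignVerdicts <- function(cand, reads, genome, cfg) {
  n <- nrow(cand)
  if (is.null(reads)) return(rep(FALSE, n))
  memo <- new.env(parent = emptyenv())
  vapply(seq_len(n), function(i) {
    so <- cand$support_obs[[i]]
    if (is.null(so) || !nrow(so)) return(FALSE)
    idx <- match(so$rid, reads$rid)
    if (anyNA(idx)) return(FALSE)
    seqs <- substring(reads$seq[idx], so$seg_qstart, so$seg_qend)
    hits <- lapply(seqs, function(s) {
      key <- s
      if (!is.null(memo[[key]])) return(memo[[key]])
      h <- realignRead(s, genome)
      memo[[key]] <- h
      h
    })
    qualifyingFraction(cand$chrom[i], cand$pos[i], hits,
                       secondRatio = cfg@secondHitRatio,
                       minFraction = cfg@qualifyFraction)$pass
  }, logical(1))
}
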