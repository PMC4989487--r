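## Alignment input, read filtering and per-site pileup.
##
## Pre-aligned, coordinate-sorted SAM/BAM is the supported entry point.
## Reads are kept only when uniquely aligned with no suboptimal hits, PCR
## duplicates are collapsed to the highest-mapping-quality copy, and the
## first/last clipN sequencing cycles of every read are masked at pileup
## time (the records themselves are preserved for the realignment filter).

#' Read alignments from a SAM or BAM file
#'
#' SAM input is converted with \code{Rsamtools::asBam} (which sorts and
#' indexes); BAM is read directly. Unmapped, secondary and supplementary
#' records are dropped.
#'
#' @param path Path to a SAM or BAM file.
#' @return A data.frame with one row per alignment: \code{rid} (integer id),
#'   \code{qname}, \code{flag}, \code{chrom}, \code{start}, \code{end},
#'   \code{strand}, \code{mate} ("single"/"first"/"second"), \code{mapq},
#'   \code{cigar}, \code{seq}, \code{qual} (ASCII Phred+33), \code{mpos},
#'   and uniqueness tags \code{x0}, \code{x1}, \code{nh} (NA when absent).
#' @export
readAlignments <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flags,
    what = c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
             "seq", "qual", "mpos"),
    tag = c("X0", "X1", "NH"))
  res <- Rsamtools::scanBam(path, param = param)[[1]]
  n <- length(res$qname)
  if (n == 0L) return(emptyAlignmentTable())
  flag <- res$flag
  mate <- rep("single", n)
  paired <- bitwAnd(flag, 1L) > 0L
  mate[paired & bitwAnd(flag, 64L) > 0L] <- "first"
  mate[paired & bitwAnd(flag, 128L) > 0L] <- "second"
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  tagOrNA <- function(tg) {
    v <- res$tag[[tg]]
    if (is.null(v)) rep(NA_integer_, n) else as.integer(v)
  }
  data.frame(
    rid = seq_len(n), qname = res$qname, flag = flag,
    chrom = as.character(res$rname), start = res$pos,
    end = res$pos + width - 1L,
    strand = as.character(res$strand), mate = mate, mapq = res$mapq,
    cigar = res$cigar, seq = as.character(res$seq),
    qual = as.character(res$qual), mpos = res$mpos,
    x0 = tagOrNA("X0"), x1 = tagOrNA("X1"), nh = tagOrNA("NH"),
    stringsAsFactors = FALSE)
}

emptyAlignmentTable <- function() {
  data.frame(rid = integer(), qname = character(), flag = integer(),
             chrom = character(), start = integer(), end = integer(),
             strand = character(), mate = character(), mapq = integer(),
             cigar = character(), seq = character(), qual = character(),
             mpos = integer(), x0 = integer(), x1 = integer(),
             nh = integer(), stringsAsFactors = FALSE)
}

#' Filter an alignment table to unique, non-duplicate reads
#'
#' Retains only uniquely aligned reads with no suboptimal hits: when
#' best/suboptimal hit-count tags are present (X0/X1, or NH), a read must
#' report exactly one best hit and zero suboptimal hits; otherwise a
#' mapping-quality floor is applied as a fallback (with a notice). Among
#' duplicate groups (identical mapping coordinates; for pairs, identical pair
#' coordinates) only the read or pair with the highest mapping quality is
#' kept, ties broken deterministically by read name.
#'
#' @param reads Alignment data.frame from \code{\link{readAlignments}},
#'   coordinate-sorted within each chromosome.
#' @param mapqFloor Fallback mapping-quality threshold when no uniqueness
#'   tags are present.
#' @return The filtered alignment data.frame.
#' @export
filterReads <- function(reads, mapqFloor = 20L) {
  if (!nrow(reads)) return(reads)
  unsorted <- vapply(split(reads$start, reads$chrom),
                     function(p) is.unsorted(p), logical(1))
  if (any(unsorted))
    stop("input not coordinate-sorted on: ",
         paste(names(unsorted)[unsorted], collapse = ", "))
  if (any(!is.na(reads$x0))) {
    keep <- !is.na(reads$x0) & reads$x0 == 1L &
      (is.na(reads$x1) | reads$x1 == 0L)
  } else if (any(!is.na(reads$nh))) {
    keep <- !is.na(reads$nh) & reads$nh == 1L
  } else {
    message("no uniqueness tags (X0/X1, NH) found; ",
            "falling back to mapq >= ", mapqFloor)
    keep <- reads$mapq >= mapqFloor
  }
  reads <- reads[keep, , drop = FALSE]
  if (!nrow(reads)) return(reads)

  paired <- bitwAnd(reads$flag, 1L) > 0L
  keepRid <- integer(0)
  se <- reads[!paired, , drop = FALSE]
  if (nrow(se)) {
    key <- paste(se$chrom, se$start, se$end, se$strand)
    o <- order(key, -se$mapq, se$qname)
    se <- se[o, , drop = FALSE]
    keepRid <- c(keepRid, se$rid[!duplicated(key[o])])
  }
  pe <- reads[paired, , drop = FALSE]
  if (nrow(pe)) {
    ## duplicate pairs share their pair footprint; score a pair by total mapq
    pkey <- paste(pe$chrom, pmin(pe$start, pe$mpos), pmax(pe$start, pe$mpos))
    byq <- split(seq_len(nrow(pe)), pe$qname)
    qn <- names(byq)
    qkey <- vapply(byq, function(i) pkey[i[1]], character(1))
    qmapq <- vapply(byq, function(i) sum(pe$mapq[i]), numeric(1))
    o <- order(qkey, -qmapq, qn)
    bestQ <- qn[o][!duplicated(qkey[o])]
    keepRid <- c(keepRid, pe$rid[pe$qname %in% bestQ])
  }
  out <- reads[reads$rid %in% keepRid, , drop = FALSE]
  out[order(out$chrom, out$start, out$rid), , drop = FALSE]
}

#' Build per-site base observations from filtered alignments
#'
#' Walks the CIGAR of every read and emits one row per aligned base that
#' survives the quality gate: bases with quality below \code{minBaseQual},
#' N bases, and bases in the first or last \code{clipN} sequencing cycles of
#' a read are excluded; deletion/intron cycles contribute nothing.
#'
#' @param reads Filtered alignment data.frame (\code{\link{filterReads}}).
#' @param genome A \code{DNAStringSet} (or path to a FASTA file).
#' @param minBaseQual Minimum Phred base quality retained.
#' @param clipN Number of sequencing cycles masked at each read end.
#' @param region Optional \code{GRanges} of length 1 restricting output.
#' @return A data.frame of base observations: \code{chrom}, \code{pos},
#'   \code{base}, \code{qual}, \code{rid}, \code{read_pos} (sequencing
#'   cycle), \code{read_len}, \code{read_start}, \code{read_end},
#'   \code{read_strand}, \code{mate}, \code{seg_qstart}, \code{seg_qend}
#'   (query range of the contiguous aligned block containing the base).
#' @export
pileupObservations <- function(reads, genome, minBaseQual = 0L, clipN = 6L,
                               region = NULL) {
  genome <- loadGenome(genome)
  if (!nrow(reads)) return(emptyPileupTable())
  bad <- setdiff(unique(reads$chrom), names(genome))
  if (length(bad))
    stop("chromosome absent from genome: ", paste(bad, collapse = ", "))

  ops <- c("M", "=", "X")
  refR <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    reads$cigar, pos = reads$start, ops = ops)
  qryR <- GenomicAlignments::cigarRangesAlongQuerySpace(reads$cigar, ops = ops)
  nblk <- S4Vectors::elementNROWS(refR)
  refU <- unlist(refR, use.names = FALSE)
  qryU <- unlist(qryR, use.names = FALSE)
  blkRead <- rep(seq_len(nrow(reads)), nblk)

  w <- IRanges::width(refU)
  baseBlk <- rep(seq_along(w), w)             # block index per emitted base
  off <- sequence(w) - 1L
  gpos <- rep(IRanges::start(refU), w) + off
  qpos <- rep(IRanges::start(qryU), w) + off
  ridx <- blkRead[baseBlk]

  readLen <- nchar(reads$seq)
  rl <- readLen[ridx]
  base <- substring(reads$seq[ridx], qpos, qpos)
  qints <- unlist(as(Biostrings::PhredQuality(
    Biostrings::BStringSet(reads$qual)), "IntegerList"), use.names = FALSE)
  qoffset <- cumsum(readLen) - readLen
  qual <- qints[qoffset[ridx] + qpos]

  ## sequencing cycle: reverse-strand SEQ is stored on the reference strand
  minus <- reads$strand[ridx] == "-"
  cycle <- ifelse(minus, rl - qpos + 1L, qpos)

  keep <- base %in% BASES & qual >= minBaseQual &
    cycle > clipN & cycle <= rl - clipN
  obs <- data.frame(
    chrom = reads$chrom[ridx][keep], pos = gpos[keep], base = base[keep],
    qual = qual[keep], rid = reads$rid[ridx][keep],
    read_pos = cycle[keep], read_len = rl[keep],
    read_start = reads$start[ridx][keep], read_end = reads$end[ridx][keep],
    read_strand = reads$strand[ridx][keep], mate = reads$mate[ridx][keep],
    seg_qstart = rep(IRanges::start(qryU), w)[keep],
    seg_qend = rep(IRanges::end(qryU), w)[keep],
    stringsAsFactors = FALSE)
  if (!is.null(region)) {
    stopifnot(is(region, "GRanges"), length(region) == 1L)
    inReg <- obs$chrom == as.character(GenomicRanges::seqnames(region)) &
      obs$pos >= GenomicRanges::start(region) &
      obs$pos <= GenomicRanges::end(region)
    obs <- obs[inReg, , drop = FALSE]
  }
  obs[order(obs$chrom, obs$pos, obs$rid), , drop = FALSE]
}

emptyPileupTable <- function() {
  data.frame(chrom = character(), pos = integer(), base = character(),
             qual = integer(), rid = integer(), read_pos = integer(),
             read_len = integer(), read_start = integer(),
             read_end = integer(), read_strand = character(),
             mate = character(), seg_qstart = integer(),
             seg_qend = integer(), stringsAsFactors = FALSE)
}

loadGenome <- function(genome) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(is(genome, "DNAStringSet"))
  genome
}

#' Assemble the observation stacks at one site
#'
#' @param dnaObs,rnaObs Pileup tables (\code{\link{pileupObservations}}).
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @param chrom,pos Site coordinates.
#' @return A \linkS4class{SiteObservations}.
#' @export
siteObservationsAt <- function(dnaObs, rnaObs, genome, chrom, pos) {
  genome <- loadGenome(genome)
  ref <- as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
  pick <- function(obs) {
    obs[obs$chrom == chrom & obs$pos == pos,
        setdiff(names(obs), c("chrom", "pos")), drop = FALSE]
  }
  siteObservations(chrom, pos, ref, dna = pick(dnaObs), rna = pick(rnaObs))
}

#' Mean genome-wide DNA depth over covered positions
#'
#' @param dnaObs DNA pileup table.
#' @return Mean number of observations per covered (chrom, pos).
#' @export
meanCoveredDepth <- function(dnaObs) {
  if (!nrow(dnaObs)) return(0)
  key <- paste(dnaObs$chrom, dnaObs$pos)
  nrow(dnaObs) / length(unique(key))
}
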