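## Self-contained simulator: random genome with multi-exon genes, planted
## heterozygous SNPs and editing sites with known levels, quality-dependent
## base errors, PCR duplicates, an optional paralogous decoy region, and
## truth-aligned reads (no external aligner needed: the supported pipeline
## entry point is pre-aligned reads).

#' Simulate a reference genome and gene models
#'
#' Generates a random genome with \code{nGenes} multi-exon genes (2-4 exons,
#' alternating strands) and, when \code{paralogIdentity > 0}, an intergenic
#' decoy copy of the first gene's leading region at the configured identity.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @return A list: \code{genome} (\code{DNAStringSet}), \code{exons} and
#'   \code{cds} data.frames (gene_id, transcript_id, chrom, strand, start,
#'   end, exon_number), \code{paralog} (data.frame with the source and copy
#'   intervals, or NULL), \code{cfg}.
#' @export
simulateReference <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  set.seed(cfg@seed)
  glen <- cfg@genomeLen
  chrom <- "chr1"
  seqv <- sample(BASES, glen, replace = TRUE)

  slot <- glen %/% cfg@nGenes
  if (slot < 1200L) stop("infeasible gene packing: ",
                         "genome too short for ", cfg@nGenes, " genes")
  exRows <- list(); cdsRows <- list()
  for (g in seq_len(cfg@nGenes)) {
    slotStart <- (g - 1L) * slot + 1L
    avail <- slot - 400L
    repeat {
      nEx <- sample(2:4, 1)
      exLens <- sample(150:300, nEx, replace = TRUE)
      inLens <- sample(80:250, nEx - 1L, replace = TRUE)
      if (sum(exLens) + sum(inLens) <= avail) break
    }
    strand <- if (g %% 2L == 1L) "+" else "-"
    gid <- sprintf("gene%02d", g); tid <- sprintf("tx%02d", g)
    pos <- slotStart + 200L
    for (i in seq_len(nEx)) {
      exRows[[length(exRows) + 1L]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = chrom, strand = strand,
        start = pos, end = pos + exLens[i] - 1L, exon_number = i,
        stringsAsFactors = FALSE)
      pos <- pos + exLens[i] + if (i < nEx) inLens[i] else 0L
    }
    ## CDS = exon chain trimmed at the transcript 3' end to a 3-multiple
    ex <- do.call(rbind, exRows[(length(exRows) - nEx + 1L):length(exRows)])
    trim <- sum(ex$end - ex$start + 1L) %% 3L
    cds <- ex
    if (trim > 0L) {
      if (strand == "+") {
        cds$end[nEx] <- cds$end[nEx] - trim
      } else {
        cds$start[1L] <- cds$start[1L] + trim
      }
    }
    for (i in seq_len(nEx))
      cdsRows[[length(cdsRows) + 1L]] <-
        cbind(cds[i, , drop = FALSE], frame = NA_integer_)
  }
  exons <- do.call(rbind, exRows); rownames(exons) <- NULL
  cds <- do.call(rbind, cdsRows); rownames(cds) <- NULL

  paralog <- NULL
  if (cfg@paralogIdentity > 0) {
    srcStart <- exons$start[1L]
    srcEnd <- srcStart + cfg@paralogLen - 1L
    cpStart <- glen - cfg@paralogLen - 50L
    cpEnd <- cpStart + cfg@paralogLen - 1L
    if (cpStart <= max(exons$end) + 200L || srcEnd > glen)
      stop("infeasible gene packing: no room for the paralog decoy")
    cp <- seqv[srcStart:srcEnd]
    nMut <- rbinom(1L, cfg@paralogLen, 1 - cfg@paralogIdentity)
    mutAt <- sample.int(cfg@paralogLen, nMut)
    for (i in mutAt) cp[i] <- sample(setdiff(BASES, cp[i]), 1L)
    seqv[cpStart:cpEnd] <- cp
    paralog <- data.frame(chrom = chrom, src_start = srcStart,
                          src_end = srcEnd, copy_start = cpStart,
                          copy_end = cpEnd,
                          identity = 1 - nMut / cfg@paralogLen,
                          n_subst = nMut, stringsAsFactors = FALSE)
  }
  genome <- Biostrings::DNAStringSet(paste(seqv, collapse = ""))
  names(genome) <- chrom
  list(genome = genome, exons = exons, cds = cds, paralog = paralog,
       cfg = cfg)
}

#' Plant heterozygous SNPs and editing sites
#'
#' SNPs are placed genome-wide at \code{hetSnpRate} per bp with a valid
#' heterozygous genotype for the configured ploidy (1..ploidy-1 alternative
#' copies). Editing sites are placed on transcript strands (genomic A for
#' plus-strand genes, genomic T for minus-strand genes, edited to G/C) in
#' exon interiors, away from homopolymer runs and transcript ends, with true
#' levels drawn uniformly from the configured range. SNP and edit positions
#' are disjoint.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param ref Reference list from \code{\link{simulateReference}}.
#' @return A list: \code{snps} (chrom, pos, ref, alt, alt_copies, genotype),
#'   \code{edits} (chrom, pos, strand, ref, edited, true_level, gene_id,
#'   transcript_id), \code{paralog}.
#' @export
plantTruth <- function(cfg, ref) {
  set.seed(cfg@seed + 1L)
  chrom <- names(ref$genome)[1]
  seqv <- strsplit(as.character(ref$genome[[1]]), "")[[1]]
  glen <- length(seqv)

  nSnp <- rbinom(1L, glen, cfg@hetSnpRate)
  snpPos <- sort(sample.int(glen, nSnp))
  snpRef <- seqv[snpPos]
  snpAlt <- vapply(snpRef, function(b) sample(setdiff(BASES, b), 1L),
                   character(1))
  copies <- if (cfg@ploidy == 2L) rep(1L, nSnp) else
    sample.int(cfg@ploidy - 1L, nSnp, replace = TRUE)
  gstr <- vapply(seq_len(nSnp), function(i) {
    paste(sort(c(rep(snpRef[i], cfg@ploidy - copies[i]),
                 rep(snpAlt[i], copies[i]))), collapse = "")
  }, character(1))
  snps <- data.frame(chrom = rep(chrom, nSnp), pos = snpPos,
                     ref = as.character(snpRef),
                     alt = as.character(snpAlt),
                     alt_copies = as.integer(copies), genotype = gstr,
                     stringsAsFactors = FALSE)

  ## eligible edit positions: exon interiors, reference A on the transcript
  ## strand, outside homopolymer runs, clear of transcript ends and SNPs
  txs <- transcriptLayout(ref$exons)
  elig <- list()
  for (tid in names(txs)) {
    tx <- txs[[tid]]
    tpos <- seq_len(tx$len)
    ok <- tpos > cfg@readLen & tpos <= tx$len - cfg@readLen
    gpos <- tx$gmap[tpos[ok]]
    want <- if (tx$strand == "+") "A" else "T"
    gpos <- gpos[seqv[gpos] == want]
    gpos <- setdiff(gpos, snpPos)
    if (length(gpos))
      elig[[tid]] <- data.frame(pos = gpos, transcript_id = tid,
                                gene_id = tx$gene_id, strand = tx$strand,
                                stringsAsFactors = FALSE)
  }
  elig <- do.call(rbind, elig)
  if (is.null(elig) || !nrow(elig)) stop("no eligible editing positions")
  hp <- vapply(elig$pos, function(p) {
    homopolymerFilter(ref$genome, chrom, p, 5L)
  }, logical(1))
  elig <- elig[hp, , drop = FALSE]
  if (nrow(elig) < cfg@nEditSites)
    stop("demand exceeds available editing positions: ", nrow(elig),
         " eligible, ", cfg@nEditSites, " requested")
  pick <- elig[sample.int(nrow(elig), cfg@nEditSites), , drop = FALSE]
  pick <- pick[order(pick$pos), , drop = FALSE]
  edits <- data.frame(
    chrom = chrom, pos = pick$pos, strand = pick$strand,
    ref = seqv[pick$pos],
    edited = ifelse(pick$strand == "+", "G", "C"),
    true_level = runif(cfg@nEditSites, cfg@editLevelMin, cfg@editLevelMax),
    gene_id = pick$gene_id, transcript_id = pick$transcript_id,
    stringsAsFactors = FALSE)
  rownames(edits) <- NULL
  list(snps = snps, edits = edits, paralog = ref$paralog)
}

## Per-transcript layout: gmap maps transcript coordinates (genomic-forward
## order along the concatenated exons) to genomic positions.
transcriptLayout <- function(exons) {
  out <- list()
  for (tid in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tid, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    gmap <- unlist(lapply(seq_len(nrow(ex)),
                          function(i) ex$start[i]:ex$end[i]))
    out[[tid]] <- list(gene_id = ex$gene_id[1], strand = ex$strand[1],
                       chrom = ex$chrom[1], exons = ex,
                       gmap = gmap, len = length(gmap))
  }
  out
}

#' Simulate sequencing reads
#'
#' DNA reads are drawn uniformly over the genome; RNA reads are drawn
#' uniformly within transcripts and carry spliced (N-gap) CIGARs. At SNPs,
#' alleles are drawn per the planted genotype proportions; at editing sites,
#' RNA reads carry the edited base with probability equal to the true level.
#' Base qualities follow the configured profile and errors are injected at
#' \code{10^(-q/10)} per base; PCR duplicates re-sequence the same fragment.
#' Strand-specific (dUTP, single-end) RNA reads are antisense to the
#' transcript.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param ref Reference from \code{\link{simulateReference}}.
#' @param truth Truth tables from \code{\link{plantTruth}}.
#' @param layer "DNA" or "RNA".
#' @param seed RNG seed for this read layer; defaults to \code{cfg@seed + 2}
#'   (DNA) or \code{cfg@seed + 3} (RNA) so that samples can be re-drawn by
#'   passing a different seed over the same truth.
#' @param library RNA library type (RNA layer only).
#' @return A data.frame of truth-aligned reads: \code{qname}, \code{flag},
#'   \code{chrom}, \code{pos}, \code{mapq}, \code{cigar}, \code{seq}
#'   (reference-strand orientation, as in SAM), \code{qual} (ASCII
#'   Phred+33), \code{strand}.
#' @export
simulateReads <- function(cfg, ref, truth, layer = c("DNA", "RNA"),
                          seed = NULL,
                          library = c("stranded_dUTP", "unstranded")) {
  layer <- match.arg(layer)
  library <- match.arg(library)
  if (is.null(seed)) seed <- cfg@seed + if (layer == "DNA") 2L else 3L
  set.seed(seed)
  chrom <- names(ref$genome)[1]
  gseq <- as.character(ref$genome[[1]])
  glen <- nchar(gseq)
  L <- cfg@readLen
  p <- cfg@ploidy
  snps <- truth$snps

  if (layer == "DNA") {
    nFrag <- round(glen * cfg@dnaDepth / L)
    starts <- sample.int(glen - L + 1L, nFrag, replace = TRUE)
    frag <- substring(gseq, starts, starts + L - 1L)
    strand <- sample(c("+", "-"), nFrag, replace = TRUE)
    cigar <- rep(sprintf("%dM", L), nFrag)
    ends <- starts + L - 1L
    ## draw SNP alleles per genotype proportions
    for (j in seq_len(nrow(snps))) {
      sp <- snps$pos[j]
      idx <- which(starts <= sp & ends >= sp)
      if (!length(idx)) next
      isAlt <- runif(length(idx)) < snps$alt_copies[j] / p
      for (i in idx[isAlt])
        substr(frag[i], sp - starts[i] + 1L, sp - starts[i] + 1L) <-
          snps$alt[j]
    }
  } else {
    txs <- transcriptLayout(ref$exons)
    txIds <- names(txs)
    txLen <- vapply(txs, function(t) t$len, integer(1))
    usable <- pmax(txLen - L + 1L, 0L)
    nFrag <- round(sum(txLen) * cfg@rnaDepth / L)
    pickTx <- sample(txIds, nFrag, replace = TRUE, prob = usable)
    starts <- integer(nFrag); frag <- character(nFrag)
    cigar <- character(nFrag); strand <- character(nFrag)
    ends <- integer(nFrag)
    snpByTx <- list(); editByTx <- list()
    txSeq <- vapply(txIds, function(tid) {
      paste(substring(gseq, txs[[tid]]$exons$start, txs[[tid]]$exons$end),
            collapse = "")
    }, character(1))
    for (tid in txIds) {
      gmap <- txs[[tid]]$gmap
      snpByTx[[tid]] <- match(snps$pos, gmap)
      editByTx[[tid]] <- match(truth$edits$pos, gmap)
    }
    for (i in seq_len(nFrag)) {
      tid <- pickTx[i]; tx <- txs[[tid]]
      s <- sample.int(tx$len - L + 1L, 1L)
      e <- s + L - 1L
      sq <- substr(txSeq[[tid]], s, e)
      tSnp <- snpByTx[[tid]]
      hitSnp <- which(!is.na(tSnp) & tSnp >= s & tSnp <= e)
      for (j in hitSnp) {
        if (runif(1) < snps$alt_copies[j] / p)
          substr(sq, tSnp[j] - s + 1L, tSnp[j] - s + 1L) <- snps$alt[j]
      }
      tEd <- editByTx[[tid]]
      hitEd <- which(!is.na(tEd) & tEd >= s & tEd <= e)
      for (j in hitEd) {
        if (runif(1) < truth$edits$true_level[j])
          substr(sq, tEd[j] - s + 1L, tEd[j] - s + 1L) <-
            truth$edits$edited[j]
      }
      frag[i] <- sq
      ## spliced genomic footprint of transcript window [s, e]
      ex <- tx$exons
      txs0 <- cumsum(c(0L, ex$end - ex$start + 1L))
      parts <- character(0); gap <- integer(0)
      gs <- NA_integer_; ge <- NA_integer_
      for (k in seq_len(nrow(ex))) {
        es <- txs0[k] + 1L; ee <- txs0[k + 1L]
        if (ee < s || es > e) next
        bs <- ex$start[k] + max(s, es) - es
        be <- ex$start[k] + min(e, ee) - es
        if (is.na(gs)) gs <- bs
        if (!is.na(ge)) gap <- c(gap, bs - ge - 1L)
        parts <- c(parts, sprintf("%dM", be - bs + 1L))
        ge <- be
      }
      cig <- parts[1]
      if (length(parts) > 1L)
        for (k in 2:length(parts))
          cig <- paste0(cig, sprintf("%dN", gap[k - 1L]), parts[k])
      starts[i] <- gs; ends[i] <- ge; cigar[i] <- cig
      strand[i] <- if (library == "stranded_dUTP") {
        if (tx$strand == "+") "-" else "+"   # single-end dUTP: antisense
      } else {
        sample(c("+", "-"), 1L)
      }
    }
  }

  ## PCR duplicates: re-sequence a sampled subset of fragments
  nDup <- rbinom(1L, nFrag, cfg@dupRate)
  dupOf <- if (nDup > 0L) sample.int(nFrag, nDup, replace = TRUE) else
    integer(0)
  allIdx <- c(seq_len(nFrag), dupOf)
  qname <- c(sprintf("%s_r%06d", tolower(layer), seq_len(nFrag)),
             if (nDup > 0L) sprintf("%s_r%06d_dup%d", tolower(layer), dupOf,
                                    seq_along(dupOf)))
  frag <- frag[allIdx]; starts <- starts[allIdx]; ends <- ends[allIdx]
  cigar <- cigar[allIdx]; strand <- strand[allIdx]
  nAll <- length(allIdx)

  ## per-copy base qualities and sequencing errors
  qmat <- matrix(pmin(pmax(round(rnorm(nAll * L, cfg@qualMean, cfg@qualSd)),
                           2L), 40L), nrow = nAll)
  errMask <- matrix(runif(nAll * L) < phredToError(qmat), nrow = nAll)
  errIdx <- which(errMask, arr.ind = TRUE)
  for (r in seq_len(nrow(errIdx))) {
    i <- errIdx[r, 1L]; j <- errIdx[r, 2L]
    cur <- substr(frag[i], j, j)
    substr(frag[i], j, j) <- sample(setdiff(BASES, cur), 1L)
  }
  qual <- vapply(seq_len(nAll),
                 function(i) intToUtf8(qmat[i, ] + 33L), character(1))

  data.frame(qname = qname, flag = ifelse(strand == "-", 16L, 0L),
             chrom = chrom, pos = starts, mapq = 37L, cigar = cigar,
             seq = frag, qual = qual, strand = strand,
             stringsAsFactors = FALSE)
}

#' Write simulated reads as SAM
#'
#' Emits an unsorted SAM with proper header and BWA-style uniqueness tags
#' (X0:i:1 X1:i:0); reading it back through \code{\link{readAlignments}}
#' sorts it.
#'
#' @param reads Read data.frame from \code{\link{simulateReads}}.
#' @param genome The reference \code{DNAStringSet}.
#' @param path Output SAM path.
#' @return Invisibly, \code{path}.
#' @export
writeSam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome),
                   Biostrings::width(genome)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s\tX0:i:1\tX1:i:0",
                  reads$qname, reads$flag, reads$chrom, reads$pos,
                  reads$mapq, reads$cigar, reads$seq, reads$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated reads as FASTQ
#'
#' Reads on the minus strand are reverse-complemented back into sequencing
#' orientation (qualities reversed accordingly).
#'
#' @param reads Read data.frame from \code{\link{simulateReads}}.
#' @param path Output FASTQ path.
#' @return Invisibly, \code{path}.
#' @export
writeFastq <- function(reads, path) {
  seqs <- reads$seq; quals <- reads$qual
  minus <- reads$strand == "-"
  seqs[minus] <- revComp(seqs[minus])
  quals[minus] <- vapply(quals[minus], function(q) {
    intToUtf8(rev(utf8ToInt(q)))
  }, character(1))
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- reads$qname
  Biostrings::writeXStringSet(dna, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Export simulated gene models as GTF
#'
#' @param ref Reference from \code{\link{simulateReference}}.
#' @param path Output GTF path.
#' @return Invisibly, \code{path}.
#' @export
exportSimGtf <- function(ref, path) {
  mk <- function(df, type) {
    gr <- GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand)
    gr$type <- type
    gr$gene_id <- df$gene_id
    gr$transcript_id <- df$transcript_id
    gr
  }
  cds <- ref$cds
  cds$phase <- NA_integer_
  for (tid in unique(cds$transcript_id)) {
    i <- which(cds$transcript_id == tid)
    i <- i[order(cds$start[i])]
    if (cds$strand[i[1]] == "-") i <- rev(i)
    lens <- cds$end[i] - cds$start[i] + 1L
    before <- cumsum(c(0L, lens[-length(lens)]))
    cds$phase[i] <- (3L - before %% 3L) %% 3L
  }
  cdsGr <- mk(cds, "CDS")
  cdsGr$phase <- cds$phase
  exGr <- mk(ref$exons, "exon")
  exGr$phase <- NA_integer_
  gr <- c(exGr, cdsGr)
  gr <- sort(gr, ignore.strand = TRUE)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Generate a complete simulated dataset on disk
#'
#' One-stop fixture builder: simulates the reference, plants the truth,
#' simulates DNA and RNA reads and writes genome.fa, genes.gtf,
#' truth_snps.tsv, truth_edits.tsv, dna.sam, rna.sam, dna.fastq and
#' rna.fastq under \code{dir}.
#'
#' @param cfg A \linkS4class{SimConfig}.
#' @param dir Output directory (created if needed).
#' @param truth Optional pre-built truth tables (to share planted sites
#'   across samples while re-drawing reads).
#' @param readSeed Optional base seed for the read layers (DNA uses
#'   \code{readSeed}, RNA \code{readSeed + 1}); defaults to the config's
#'   scheme.
#' @param library RNA library type.
#' @return A list with the simulation objects and all file \code{paths}.
#' @export
simulateDataset <- function(cfg, dir, truth = NULL, readSeed = NULL,
                            library = "stranded_dUTP") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulateReference(cfg)
  if (is.null(truth)) truth <- plantTruth(cfg, ref)
  dnaSeed <- if (is.null(readSeed)) NULL else readSeed
  rnaSeed <- if (is.null(readSeed)) NULL else readSeed + 1L
  dna <- simulateReads(cfg, ref, truth, "DNA", seed = dnaSeed)
  rna <- simulateReads(cfg, ref, truth, "RNA", seed = rnaSeed,
                       library = library)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    gtf = file.path(dir, "genes.gtf"),
    snps = file.path(dir, "truth_snps.tsv"),
    edits = file.path(dir, "truth_edits.tsv"),
    dnaSam = file.path(dir, "dna.sam"),
    rnaSam = file.path(dir, "rna.sam"),
    dnaFastq = file.path(dir, "dna.fastq"),
    rnaFastq = file.path(dir, "rna.fastq"))
  Biostrings::writeXStringSet(ref$genome, paths$genome)
  exportSimGtf(ref, paths$gtf)
  write.table(truth$snps, paths$snps, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$edits, paths$edits, sep = "\t", quote = FALSE,
              row.names = FALSE)
  writeSam(dna, ref$genome, paths$dnaSam)
  writeSam(rna, ref$genome, paths$rnaSam)
  writeFastq(dna, paths$dnaFastq)
  writeFastq(rna, paths$rnaFastq)
  list(ref = ref, truth = truth, dnaReads = dna, rnaReads = rna,
       paths = paths, cfg = cfg)
}
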