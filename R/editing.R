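## Candidate editing-site detection and the false-positive filter cascade.
##
## A candidate needs at least minSupportReads non-redundant supporting RNA
## reads (distinct mapping footprints) and an editing level of at least
## minEditingLevel; it then has to survive eleven checks: DNA homozygosity,
## known-SNP exclusion, single editing type, support, level, mid-read
## support, splice distance, homopolymer, DNA depth cap, realignment
## qualification and the binomial sequencing-error test under BH FDR.

CASCADE_FILTERS <- c("dna_homozygous", "known_snp_excluded", "multi_type",
                     "support", "level", "mid_read", "splice_distance",
                     "homopolymer", "depth_cap", "realign_qualified",
                     "fdr_pass")

#' Detect candidate editing sites from matched pileups
#'
#' Scans the RNA pileup for sites with a single alternative base carried by
#' enough non-redundant reads. Non-redundancy collapses reads with identical
#' mapping footprints (start, end, strand, mate) so PCR-duplicate-driven
#' support cannot count twice; both the supporting count k and the total
#' depth n are non-redundant counts.
#'
#' @param rnaObs RNA pileup table (already quality-filtered at pileup time).
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @param cfg A \linkS4class{FilterConfig}.
#' @param emitAll Emit every mismatch-bearing site regardless of the support
#'   and level thresholds (their verdicts are recorded either way); default
#'   FALSE applies the thresholds at emission, the pipeline's basic criteria.
#' @return A data.frame of candidates: \code{chrom}, \code{pos},
#'   \code{ref_base}, \code{alt_base}, \code{n_total}, \code{k_edited},
#'   \code{editing_level}, \code{n_alt_types}, verdict columns
#'   \code{multi_type}, \code{support}, \code{level}, and a list-column
#'   \code{support_obs} of the non-redundant supporting observations.
#' @export
detectCandidates <- function(rnaObs, genome, cfg = filterConfig(),
                             emitAll = FALSE) {
  genome <- loadGenome(genome)
  empty <- data.frame(chrom = character(), pos = integer(),
                      ref_base = character(), alt_base = character(),
                      n_total = integer(), k_edited = integer(),
                      editing_level = numeric(), n_alt_types = integer(),
                      multi_type = logical(), support = logical(),
                      level = logical(), stringsAsFactors = FALSE)
  empty$support_obs <- list()
  if (!nrow(rnaObs)) return(empty)

  ## non-redundant footprint per observation
  fp <- paste(rnaObs$read_start, rnaObs$read_end, rnaObs$read_strand,
              rnaObs$mate)
  o <- order(rnaObs$chrom, rnaObs$pos, fp, -rnaObs$qual)
  obs <- rnaObs[o, , drop = FALSE]
  dupkey <- paste(obs$chrom, obs$pos, fp[o])
  obs <- obs[!duplicated(dupkey), , drop = FALSE]

  ## fast pre-screen: only sites with >= 1 mismatch need per-site work
  refAll <- refBaseAt(genome, obs$chrom, obs$pos)
  mmSites <- unique(paste(obs$chrom, obs$pos)[obs$base != refAll &
                                                refAll %in% BASES])
  if (!length(mmSites)) return(empty)
  siteKey <- paste(obs$chrom, obs$pos)
  obs <- obs[siteKey %in% mmSites, , drop = FALSE]
  siteKey <- paste(obs$chrom, obs$pos)

  rows <- lapply(split(seq_len(nrow(obs)), siteKey), function(i) {
    so <- obs[i, , drop = FALSE]
    ref <- refBaseAt(genome, so$chrom[1], so$pos[1])
    counts <- table(factor(so$base, levels = BASES))
    altCounts <- counts[setdiff(BASES, ref)]
    altCounts <- altCounts[altCounts > 0]
    if (!length(altCounts)) return(NULL)
    alt <- names(altCounts)[order(-altCounts, names(altCounts))][1]
    k <- as.integer(altCounts[[alt]])
    n <- nrow(so)
    lvl <- k / n
    sup <- k >= cfg@minSupportReads
    lvlOk <- lvl >= cfg@minEditingLevel
    if (!emitAll && !(sup && lvlOk)) return(NULL)
    out <- data.frame(chrom = so$chrom[1], pos = so$pos[1], ref_base = ref,
                      alt_base = alt, n_total = n, k_edited = k,
                      editing_level = lvl,
                      n_alt_types = length(altCounts),
                      multi_type = length(altCounts) < 2L,
                      support = sup, level = lvlOk,
                      stringsAsFactors = FALSE)
    out$support_obs <- list(so[so$base == alt, , drop = FALSE])
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$chrom, cand$pos), , drop = FALSE]
  rownames(cand) <- NULL
  cand
}

refBaseAt <- function(genome, chrom, pos) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    i <- chrom == ch
    out[i] <- as.character(Biostrings::extractAt(
      genome[[ch]], IRanges::IRanges(pos[i], pos[i])))
  }
  out
}

#' Label the editing type on the transcript strand
#'
#' A genomic T-to-C change on a minus-strand transcript is an A-to-G edit on
#' the transcript; strand "." reports the change on the plus-strand
#' convention.
#'
#' @param ref,alt Reference and edited base on the genomic plus strand.
#' @param transcriptStrand "+", "-" or ".".
#' @return Label such as "A-to-G".
#' @examples
#' inferEditType("T", "C", "-")  # "A-to-G"
#' @export
inferEditType <- function(ref, alt, transcriptStrand = "+") {
  if (ref == alt) stop("ref and alt must differ")
  if (transcriptStrand == "-") {
    ref <- unname(complementBase(ref)); alt <- unname(complementBase(alt))
  }
  paste0(ref, "-to-", alt)
}

#' Infer the transcript strand of a candidate
#'
#' For strand-specific dUTP libraries the strand comes from the orientation
#' of the supporting reads: the second-in-pair read matches the transcript
#' strand, while single-end and first-in-pair reads are antisense (the
#' standard dUTP convention; \code{invertStrandRule} flips it). For
#' unstranded libraries the strand is taken from a uniquely overlapping gene
#' model, else ".".
#'
#' @param supportObs Supporting observation rows of the candidate.
#' @param library "stranded_dUTP" or "unstranded".
#' @param geneStrand Strand(s) of overlapping gene(s) for unstranded data.
#' @param invertStrandRule Flip the dUTP orientation convention.
#' @return "+", "-" or ".".
#' @export
inferTranscriptStrand <- function(supportObs,
                                  library = c("stranded_dUTP", "unstranded"),
                                  geneStrand = character(),
                                  invertStrandRule = FALSE) {
  library <- match.arg(library)
  if (library == "unstranded") {
    gs <- unique(geneStrand[geneStrand %in% c("+", "-")])
    return(if (length(gs) == 1L) gs else ".")
  }
  if (!nrow(supportObs)) return(".")
  flip <- function(s) ifelse(s == "+", "-", "+")
  votes <- ifelse(supportObs$mate == "second",
                  supportObs$read_strand, flip(supportObs$read_strand))
  if (invertStrandRule) votes <- flip(votes)
  names(which.max(table(votes)))
}

#' The mid-read window of a read
#'
#' The central half of the read: positions \code{floor(L/4)+1} through
#' \code{L - floor(L/4)}; for a 90-bp read, positions 23 to 68. At least one
#' supporting read must carry the candidate site inside this window.
#'
#' @param readLen Read length in bp (>= 4).
#' @return Integer vector \code{c(first, last)}, 1-based inclusive.
#' @examples
#' midReadWindow(90)  # c(23, 68)
#' @export
midReadWindow <- function(readLen) {
  readLen <- as.integer(readLen)
  if (is.na(readLen) || readLen < 4L) stop("readLen must be >= 4")
  q <- readLen %/% 4L
  c(q + 1L, readLen - q)
}

midReadVerdict <- function(supportObs) {
  if (!nrow(supportObs)) return(FALSE)
  any(vapply(seq_len(nrow(supportObs)), function(i) {
    w <- midReadWindow(supportObs$read_len[i])
    supportObs$read_pos[i] >= w[1] && supportObs$read_pos[i] <= w[2]
  }, logical(1)))
}

#' Splice-distance filter
#'
#' Discards intronic sites within \code{spliceDist} bases of a splice
#' boundary; exonic sites are unaffected. The distance of the first intronic
#' base to its splice site is 1.
#'
#' @param chrom,pos Site coordinates.
#' @param features Feature \code{GRanges} from \code{\link{buildFeatureIndex}}
#'   (classes "exon" and "intron" are used).
#' @param spliceDist Exclusion distance in bases (default 6).
#' @return TRUE to keep, FALSE to discard.
#' @export
spliceDistanceFilter <- function(chrom, pos, features, spliceDist = 6L) {
  site <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  cls <- features$feature_class
  exonHit <- length(GenomicRanges::findOverlaps(
    site, features[cls == "exon"], ignore.strand = TRUE)) > 0L
  if (exonHit) return(TRUE)
  introns <- features[cls == "intron"]
  hits <- GenomicRanges::findOverlaps(site, introns, ignore.strand = TRUE)
  if (!length(hits)) return(TRUE)  # intergenic: the rule targets introns
  iv <- introns[S4Vectors::subjectHits(hits)]
  d <- pmin(pos - GenomicRanges::start(iv) + 1L,
            GenomicRanges::end(iv) - pos + 1L)
  min(d) > spliceDist
}

#' Homopolymer filter
#'
#' Discards sites whose maximal run of identical reference bases has length
#' >= \code{homopolymerLen} (homopolymers have elevated sequencing error).
#'
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @param chrom,pos Site coordinates.
#' @param homopolymerLen Minimal discarded run length (default 5).
#' @return TRUE to keep, FALSE to discard.
#' @export
homopolymerFilter <- function(genome, chrom, pos, homopolymerLen = 5L) {
  genome <- loadGenome(genome)
  chr <- genome[[chrom]]
  L <- length(chr)
  stopifnot(pos >= 1L, pos <= L)
  lo <- max(1L, pos - homopolymerLen + 1L)
  hi <- min(L, pos + homopolymerLen - 1L)
  s <- strsplit(as.character(Biostrings::subseq(chr, lo, hi)), "")[[1]]
  center <- pos - lo + 1L
  b <- s[center]
  run <- 1L
  i <- center - 1L
  while (i >= 1L && s[i] == b) { run <- run + 1L; i <- i - 1L }
  i <- center + 1L
  while (i <= length(s) && s[i] == b) { run <- run + 1L; i <- i + 1L }
  run < homopolymerLen
}

#' DNA depth-cap filter
#'
#' Discards sites whose DNA depth exceeds \code{factor} times the
#' genome-wide mean (or peak) depth; such sites are likely collapsed copy
#' number variation.
#'
#' @param dnaDepth DNA read depth at the site.
#' @param genomeMeanDepth Genome-wide mean (or modal) covered depth.
#' @param factor Cap multiplier (default 2).
#' @return TRUE to keep (depth <= factor * mean), FALSE to discard.
#' @export
depthCapFilter <- function(dnaDepth, genomeMeanDepth, factor = 2.0) {
  stopifnot(genomeMeanDepth > 0)
  dnaDepth <= factor * genomeMeanDepth
}

#' Exact binomial sequencing-error test
#'
#' Upper-tail probability P(X >= k) for X ~ Binomial(n, pErr): the chance
#' that sequencing error alone produces at least the observed support. pErr
#' defaults to the per-base error ceiling implied by the RNA quality gate.
#'
#' @param k Supporting (edited) reads.
#' @param n Total read depth at the site.
#' @param pErr Per-base error probability.
#' @return The p-value.
#' @examples
#' binomErrorTest(3, 3, 0.001)  # 1e-9
#' @export
binomErrorTest <- function(k, n, pErr = 0.001) {
  stopifnot(pErr > 0, pErr < 1, k >= 0)
  if (any(k > n)) stop("k must not exceed n")
  pbinom(k - 1, n, pErr, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Standard BH step-up with monotonicity enforcement; output order matches
#' input order.
#'
#' @param pValues Numeric vector of p-values in [0, 1].
#' @return q-values in [0, 1].
#' @export
bhFdr <- function(pValues) {
  if (any(is.na(pValues)) || any(pValues < 0 | pValues > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(pValues, method = "BH")
}

#' Apply the full filter cascade to a candidate table
#'
#' Computes all eleven verdicts for every candidate. Verdicts are pure
#' per-site predicates except \code{fdr_pass}: binomial p-values are
#' computed for every candidate, but q-values (and hence \code{fdr_pass})
#' are computed over the candidates surviving all non-statistical filters,
#' so the correction is not diluted by already-rejected sites. The final
#' \code{pass} is the conjunction of all verdicts.
#'
#' @param cand Candidate table from \code{\link{detectCandidates}}.
#' @param context A list supplying \code{genome}, \code{dnaObs} (DNA pileup),
#'   \code{features} (feature \code{GRanges} or NULL), \code{knownSnps}
#'   (data.frame with chrom, pos, or NULL), \code{meanDnaDepth},
#'   \code{reads} (RNA alignment table, for realignment sequences) and
#'   \code{cfg} (a \linkS4class{FilterConfig}).
#' @return The candidate table with verdict columns, \code{dna_depth},
#'   \code{genotype}, \code{posterior}, \code{p_value}, \code{q_value} and
#'   \code{pass}.
#' @export
applyFilterCascade <- function(cand, context) {
  need <- c("genome", "dnaObs", "meanDnaDepth", "cfg")
  miss <- setdiff(need, names(context))
  if (length(miss))
    stop("missing context element(s): ", paste(miss, collapse = ", "))
  cfg <- context$cfg
  genome <- loadGenome(context$genome)
  if (!nrow(cand)) {
    for (col in c(CASCADE_FILTERS, "pass")) cand[[col]] <- logical(0)
    cand$p_value <- numeric(0); cand$q_value <- numeric(0)
    return(cand)
  }

  n <- nrow(cand)
  v <- list()
  gcalls <- vector("list", n)
  for (i in seq_len(n)) {
    so <- siteObservationsAt(context$dnaObs, emptyPileupTable(), genome,
                             cand$chrom[i], cand$pos[i])
    gcalls[[i]] <- callGenotype(so, cfg)
  }
  v$dna_homozygous <- vapply(gcalls, callPasses, logical(1))
  cand$dna_depth <- vapply(gcalls, dnaDepth, integer(1))
  cand$genotype <- vapply(gcalls, calledGenotype, character(1))
  cand$posterior <- vapply(gcalls, callScore, numeric(1))

  snps <- context$knownSnps
  v$known_snp_excluded <- if (is.null(snps) || !nrow(snps)) {
    rep(TRUE, n)
  } else {
    !(paste(cand$chrom, cand$pos) %in% paste(snps$chrom, snps$pos))
  }
  v$multi_type <- cand$multi_type
  v$support <- cand$support
  v$level <- cand$level
  v$mid_read <- vapply(cand$support_obs, midReadVerdict, logical(1))
  v$splice_distance <- if (is.null(context$features)) rep(TRUE, n) else
    vapply(seq_len(n), function(i) {
      spliceDistanceFilter(cand$chrom[i], cand$pos[i], context$features,
                           cfg@spliceDist)
    }, logical(1))
  v$homopolymer <- vapply(seq_len(n), function(i) {
    homopolymerFilter(genome, cand$chrom[i], cand$pos[i], cfg@homopolymerLen)
  }, logical(1))
  v$depth_cap <- depthCapFilter(cand$dna_depth, context$meanDnaDepth,
                                cfg@depthCapFactor)
  v$realign_qualified <- realignVerdicts(cand, context$reads, genome, cfg)

  cand$p_value <- binomErrorTest(cand$k_edited, cand$n_total, errRate(cfg))
  nonstat <- Reduce(`&`, v[setdiff(CASCADE_FILTERS, "fdr_pass")])
  cand$q_value <- NA_real_
  cand$q_value[nonstat] <- bhFdr(cand$p_value[nonstat])
  ## candidates rejected by a non-statistical filter never reach the
  ## statistical test: their FDR verdict is undefined (NA), not false
  v$fdr_pass <- ifelse(nonstat, cand$q_value <= cfg@fdrCutoff, NA)

  for (col in CASCADE_FILTERS) cand[[col]] <- v[[col]]
  cand$pass <- nonstat & !is.na(v$fdr_pass) & v$fdr_pass
  cand
}
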