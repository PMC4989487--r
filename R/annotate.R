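## Annotation of editing sites with genomic features and, for CDS sites,
## the codon and amino-acid change implied by the edit.

#' Build the feature index from gene models
#'
#' Collects exon, CDS and UTR features from a GTF/GFF3 (or a ready
#' \code{GRanges} with a \code{type} column), derives introns from each
#' transcript's exon chain, derives UTRs from exon minus CDS extent when not
#' given explicitly, and optionally appends repeat intervals from a BED file
#' (0-based half-open, auto-converted) or a 1-based TSV (chrom, start, end).
#'
#' @param geneModels GTF/GFF3 path or \code{GRanges}.
#' @param repeats Optional repeat intervals: BED path, 1-based TSV path, or
#'   \code{GRanges}.
#' @param repeatDialect "bed" (0-based half-open) or "tsv" (1-based
#'   inclusive) when \code{repeats} is a path.
#' @return A \code{GRanges} with metadata columns \code{feature_class}
#'   ("exon", "intron", "CDS", "5'-UTR", "3'-UTR", "repeat"),
#'   \code{gene_id}, \code{transcript_id} and \code{frame}.
#' @export
buildFeatureIndex <- function(geneModels, repeats = NULL,
                              repeatDialect = c("bed", "tsv")) {
  repeatDialect <- match.arg(repeatDialect)
  if (is.character(geneModels)) geneModels <- rtracklayer::import(geneModels)
  stopifnot(is(geneModels, "GRanges"))
  gr <- geneModels
  type <- tolower(as.character(gr$type))
  classMap <- c(exon = "exon", cds = "CDS",
                five_prime_utr = "5'-UTR", three_prime_utr = "3'-UTR",
                `5utr` = "5'-UTR", `3utr` = "3'-UTR")
  keep <- type %in% names(classMap)
  gr <- gr[keep]; type <- type[keep]

  getcol <- function(g, nm) {
    v <- S4Vectors::mcols(g)[[nm]]
    if (is.null(v)) rep(NA_character_, length(g)) else as.character(v)
  }
  feat <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::ranges(gr),
    strand = GenomicRanges::strand(gr))
  feat$feature_class <- unname(classMap[type])
  feat$gene_id <- getcol(gr, "gene_id")
  feat$transcript_id <- getcol(gr, "transcript_id")
  fr <- S4Vectors::mcols(gr)[["phase"]]
  feat$frame <- if (is.null(fr)) NA_integer_ else as.integer(as.character(fr))

  ## introns from exon chains
  exons <- feat[feat$feature_class == "exon"]
  intrList <- list()
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx]
    e <- e[order(GenomicRanges::start(e))]
    if (length(e) < 2L) next
    s <- GenomicRanges::end(e)[-length(e)] + 1L
    t <- GenomicRanges::start(e)[-1L] - 1L
    ok <- t >= s
    if (!any(ok)) next
    gi <- GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(e))[1],
      IRanges::IRanges(s[ok], t[ok]),
      strand = as.character(GenomicRanges::strand(e))[1])
    gi$feature_class <- "intron"
    gi$gene_id <- e$gene_id[1]
    gi$transcript_id <- tx
    gi$frame <- NA_integer_
    intrList[[tx]] <- gi
  }
  if (length(intrList))
    feat <- c(feat, do.call(c, unname(intrList)))

  ## UTRs from exon minus CDS extent, when the models carry CDS but no UTRs
  if (!any(feat$feature_class %in% c("5'-UTR", "3'-UTR")) &&
      any(feat$feature_class == "CDS")) {
    utrList <- list()
    for (tx in unique(feat$transcript_id[feat$feature_class == "CDS"])) {
      e <- feat[feat$feature_class == "exon" & feat$transcript_id == tx]
      cds <- feat[feat$feature_class == "CDS" & feat$transcript_id == tx]
      if (!length(e) || !length(cds)) next
      cdsLo <- min(GenomicRanges::start(cds))
      cdsHi <- max(GenomicRanges::end(cds))
      u <- GenomicRanges::setdiff(
        e, GenomicRanges::GRanges(GenomicRanges::seqnames(e)[1],
                                  IRanges::IRanges(cdsLo, cdsHi)),
        ignore.strand = TRUE)
      if (!length(u)) next
      std <- as.character(GenomicRanges::strand(e))[1]
      before <- GenomicRanges::end(u) < cdsLo
      cls <- ifelse(xor(before, std == "-"), "5'-UTR", "3'-UTR")
      GenomicRanges::strand(u) <- std
      u$feature_class <- cls
      u$gene_id <- e$gene_id[1]
      u$transcript_id <- tx
      u$frame <- NA_integer_
      utrList[[tx]] <- u
    }
    if (length(utrList))
      feat <- c(feat, do.call(c, unname(utrList)))
  }

  if (!is.null(repeats)) {
    if (is.character(repeats)) {
      if (repeatDialect == "bed") {
        repeats <- rtracklayer::import(repeats, format = "bed")
      } else {
        tab <- read.table(repeats, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
        repeats <- GenomicRanges::GRanges(
          tab[[1]], IRanges::IRanges(tab[[2]], tab[[3]]))
      }
    }
    stopifnot(is(repeats, "GRanges"))
    rp <- GenomicRanges::GRanges(GenomicRanges::seqnames(repeats),
                                 IRanges::ranges(repeats), strand = "*")
    rp$feature_class <- "repeat"
    rp$gene_id <- NA_character_
    rp$transcript_id <- NA_character_
    rp$frame <- NA_integer_
    feat <- c(feat, rp)
  }
  sort(feat, ignore.strand = TRUE)
}

#' Feature classes overlapping a site
#'
#' @param chrom,pos Site coordinates.
#' @param features Feature \code{GRanges} from \code{\link{buildFeatureIndex}}.
#' @return A data.frame of overlapping features (\code{feature_class},
#'   \code{gene_id}, \code{transcript_id}); a single "intergenic" row when
#'   nothing overlaps. A site may carry several labels across transcripts.
#' @export
annotateSite <- function(chrom, pos, features) {
  site <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, pos))
  hits <- GenomicRanges::findOverlaps(site, features, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(feature_class = "intergenic",
                      gene_id = NA_character_,
                      transcript_id = NA_character_,
                      stringsAsFactors = FALSE))
  f <- features[S4Vectors::subjectHits(hits)]
  out <- data.frame(feature_class = f$feature_class, gene_id = f$gene_id,
                    transcript_id = f$transcript_id,
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out[order(out$feature_class, out$transcript_id), , drop = FALSE]
}

#' Codon and amino-acid change of a CDS edit
#'
#' Assembles the coding sequence of the transcript from its CDS blocks
#' (honoring splicing and strand), substitutes the edited base on the coding
#' strand (complemented for minus-strand genes) and translates with the
#' standard genetic code.
#'
#' @param chrom,pos Site coordinates (genomic).
#' @param editedBase Edited base on the genomic plus strand.
#' @param transcriptId Transcript whose CDS contains the site.
#' @param features Feature \code{GRanges} from \code{\link{buildFeatureIndex}}.
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @return A list: \code{codon_before}, \code{codon_after}, \code{aa_before},
#'   \code{aa_after}, \code{synonymous}, \code{codon_position}; or NULL with
#'   a warning when the assembled CDS length is not a multiple of 3.
#' @export
codonChange <- function(chrom, pos, editedBase, transcriptId, features,
                        genome) {
  genome <- loadGenome(genome)
  cds <- features[features$feature_class == "CDS" &
                    features$transcript_id == transcriptId]
  if (!length(cds)) stop("no CDS for transcript ", transcriptId)
  cds <- cds[order(GenomicRanges::start(cds))]
  std <- as.character(GenomicRanges::strand(cds))[1]
  starts <- GenomicRanges::start(cds); ends <- GenomicRanges::end(cds)
  if (sum(ends - starts + 1L) %% 3L != 0L) {
    warning("CDS length of ", transcriptId,
            " is not a multiple of 3; no codon change inferred")
    return(NULL)
  }
  blk <- which(starts <= pos & ends >= pos)
  if (!length(blk)) stop("site not inside the CDS of ", transcriptId)

  seqs <- vapply(seq_along(starts), function(i) {
    as.character(Biostrings::subseq(genome[[chrom]], starts[i], ends[i]))
  }, character(1))
  plusCds <- paste(seqs, collapse = "")
  offPlus <- sum(ends[seq_len(blk - 1L)] - starts[seq_len(blk - 1L)] + 1L) +
    (pos - starts[blk] + 1L)
  if (std == "-") {
    cdsSeq <- revComp(plusCds)
    cdsPos <- nchar(plusCds) - offPlus + 1L
    edited <- unname(complementBase(editedBase))
  } else {
    cdsSeq <- plusCds
    cdsPos <- offPlus
    edited <- editedBase
  }
  codonIdx <- (cdsPos - 1L) %/% 3L
  codonPos <- (cdsPos - 1L) %% 3L + 1L
  codonBefore <- substr(cdsSeq, codonIdx * 3L + 1L, codonIdx * 3L + 3L)
  codonAfter <- codonBefore
  substr(codonAfter, codonPos, codonPos) <- edited
  aa <- function(cod) unname(Biostrings::GENETIC_CODE[cod])
  list(codon_before = codonBefore, codon_after = codonAfter,
       aa_before = aa(codonBefore), aa_after = aa(codonAfter),
       synonymous = aa(codonBefore) == aa(codonAfter),
       codon_position = codonPos)
}

#' Annotate a candidate table with features and codon changes
#'
#' @param cand Candidate table (needs \code{chrom}, \code{pos},
#'   \code{alt_base}).
#' @param features Feature \code{GRanges} from \code{\link{buildFeatureIndex}}.
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @return The table with \code{feature_classes}, \code{gene_id} and, for
#'   CDS sites, \code{codon_before}, \code{codon_after}, \code{aa_before},
#'   \code{aa_after}, \code{synonymous} columns.
#' @export
annotateSites <- function(cand, features, genome) {
  genome <- loadGenome(genome)
  n <- nrow(cand)
  cand$feature_classes <- character(n)
  cand$gene_id <- NA_character_
  for (col in c("codon_before", "codon_after", "aa_before", "aa_after"))
    cand[[col]] <- NA_character_
  cand$synonymous <- NA
  for (i in seq_len(n)) {
    ann <- annotateSite(cand$chrom[i], cand$pos[i], features)
    cand$feature_classes[i] <-
      paste(sort(unique(ann$feature_class)), collapse = ",")
    gid <- unique(ann$gene_id[!is.na(ann$gene_id)])
    if (length(gid)) cand$gene_id[i] <- paste(gid, collapse = ",")
    cdsTx <- unique(ann$transcript_id[ann$feature_class == "CDS"])
    cdsTx <- cdsTx[!is.na(cdsTx)]
    if (length(cdsTx)) {
      cc <- tryCatch(
        codonChange(cand$chrom[i], cand$pos[i], cand$alt_base[i],
                    cdsTx[1], features, genome),
        warning = function(w) NULL)
      if (!is.null(cc)) {
        cand$codon_before[i] <- cc$codon_before
        cand$codon_after[i] <- cc$codon_after
        cand$aa_before[i] <- cc$aa_before
        cand$aa_after[i] <- cc$aa_after
        cand$synonymous[i] <- cc$synonymous
      }
    }
  }
  cand
}
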