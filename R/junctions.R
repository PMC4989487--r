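## Splice-junction library: artificial contigs of exonic sequence flanking
## every known splice junction, plus the lift-over back to genomic
## coordinates. Flanks are one base shorter than the read length so that no
## read can hit both the genome and a junction contig simultaneously.

#' Build the splice-junction library
#'
#' For every distinct splice junction in the gene models, emits one contig
#' consisting of the last \code{readLength - 1} exonic bases upstream of the
#' junction concatenated with the first \code{readLength - 1} exonic bases
#' downstream. Junctions shared by several transcripts are emitted once.
#' Flanks truncated by exon or contig boundaries are kept and flagged
#' (\code{short_flank}).
#'
#' @param genome A \code{DNAStringSet} or FASTA path.
#' @param geneModels Gene models: a GTF/GFF3 path, a \code{GRanges} of exon
#'   features with \code{transcript_id}, or an exon data.frame with columns
#'   \code{chrom}, \code{start}, \code{end}, \code{strand},
#'   \code{transcript_id}.
#' @param readLength Sequencing read length (>= 2); flanks are
#'   \code{readLength - 1} bp.
#' @return A \linkS4class{JunctionLibrary}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = paste(rep("ACGT", 100), collapse = "")))
#' ex <- data.frame(chrom = "chr1", start = c(1, 201), end = c(100, 300),
#'                  strand = "+", transcript_id = "t1")
#' jl <- buildJunctionLibrary(g, ex, readLength = 90)
#' junctionMap(jl)$flank_length  # 89
#' @export
buildJunctionLibrary <- function(genome, geneModels, readLength) {
  readLength <- as.integer(readLength)
  if (is.na(readLength) || readLength < 2L)
    stop("readLength must be an integer >= 2")
  genome <- loadGenome(genome)
  exons <- asExonTable(geneModels)
  flank <- readLength - 1L

  emptyLib <- function() new("JunctionLibrary",
    contigs = Biostrings::DNAStringSet(),
    map = data.frame(junction_id = character(), chrom = character(),
                     left_exon_end = integer(), right_exon_start = integer(),
                     flank_length = integer(), flank_left = integer(),
                     flank_right = integer(), strand = character(),
                     short_flank = logical(), stringsAsFactors = FALSE),
    readLength = readLength)
  if (!nrow(exons)) return(emptyLib())

  rows <- list()
  for (tx in split(exons, exons$transcript_id)) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) < 2L) next
    for (i in seq_len(nrow(tx) - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$chrom[i], left_exon_end = tx$end[i],
        right_exon_start = tx$start[i + 1L],
        left_exon_start = tx$start[i], right_exon_end = tx$end[i + 1L],
        strand = tx$strand[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(emptyLib())
  jn <- do.call(rbind, rows)
  jn <- jn[!duplicated(paste(jn$chrom, jn$left_exon_end,
                             jn$right_exon_start)), , drop = FALSE]

  clen <- stats::setNames(Biostrings::width(genome), names(genome))
  ok <- jn$chrom %in% names(genome)
  ok[ok] <- jn$left_exon_end[ok] >= 1L & jn$left_exon_end[ok] <= clen[jn$chrom[ok]] &
    jn$right_exon_start[ok] >= 1L & jn$right_exon_start[ok] <= clen[jn$chrom[ok]] &
    jn$right_exon_start[ok] > jn$left_exon_end[ok]
  if (any(!ok))
    warning(sum(!ok), " junction(s) outside genome bounds skipped")
  jn <- jn[ok, , drop = FALSE]
  if (!nrow(jn)) return(emptyLib())

  ## flanks stop at the flanking exon's own boundary and at the contig edge
  flankLeft <- pmin(flank, jn$left_exon_end - jn$left_exon_start + 1L,
                    jn$left_exon_end)
  flankRight <- pmin(flank, jn$right_exon_end - jn$right_exon_start + 1L,
                     clen[jn$chrom] - jn$right_exon_start + 1L)
  seqs <- character(nrow(jn))
  for (i in seq_len(nrow(jn))) {
    chr <- genome[[jn$chrom[i]]]
    left <- Biostrings::subseq(chr, jn$left_exon_end[i] - flankLeft[i] + 1L,
                               jn$left_exon_end[i])
    right <- Biostrings::subseq(chr, jn$right_exon_start[i],
                                jn$right_exon_start[i] + flankRight[i] - 1L)
    seqs[i] <- paste0(as.character(left), as.character(right))
  }
  jid <- paste0(jn$chrom, ":", jn$left_exon_end, "-", jn$right_exon_start)
  map <- data.frame(
    junction_id = jid, chrom = jn$chrom,
    left_exon_end = jn$left_exon_end,
    right_exon_start = jn$right_exon_start,
    flank_length = flank, flank_left = as.integer(flankLeft),
    flank_right = as.integer(flankRight), strand = jn$strand,
    short_flank = flankLeft < flank | flankRight < flank,
    stringsAsFactors = FALSE)
  contigs <- Biostrings::DNAStringSet(seqs)
  names(contigs) <- jid
  new("JunctionLibrary", contigs = contigs, map = map,
      readLength = readLength)
}

asExonTable <- function(geneModels) {
  if (is.character(geneModels)) geneModels <- rtracklayer::import(geneModels)
  if (is(geneModels, "GRanges")) {
    gr <- geneModels
    if (!is.null(gr$type)) gr <- gr[tolower(gr$type) == "exon"]
    txid <- gr$transcript_id
    if (is.null(txid)) txid <- as.character(gr$Parent)
    geneModels <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      transcript_id = txid, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end", "strand", "transcript_id") %in%
                names(geneModels)))
  geneModels
}

#' Lift junction-contig offsets to genomic positions
#'
#' Offsets at or left of the junction midpoint map into the upstream exon,
#' the rest into the downstream exon:
#' \code{offset <= flank_left} maps to
#' \code{left_exon_end - (flank_left - offset)}, and larger offsets map to
#' \code{right_exon_start + (offset - flank_left - 1)}.
#'
#' @param offsets 1-based offsets on the junction contig.
#' @param mapRow One row of \code{junctionMap()}.
#' @return Integer vector of genomic positions.
#' @export
liftJunctionOffsets <- function(offsets, mapRow) {
  fl <- mapRow$flank_left
  stopifnot(all(offsets >= 1L), all(offsets <= fl + mapRow$flank_right))
  ifelse(offsets <= fl,
         mapRow$left_exon_end - (fl - offsets),
         mapRow$right_exon_start + (offsets - fl - 1L))
}

#' Project genomic positions back to junction-contig offsets
#'
#' Inverse of \code{\link{liftJunctionOffsets}}; positions outside either
#' flank yield NA.
#'
#' @param positions Genomic positions.
#' @param mapRow One row of \code{junctionMap()}.
#' @return Integer offsets (NA where the position is not on the contig).
#' @export
projectToJunction <- function(positions, mapRow) {
  fl <- mapRow$flank_left; fr <- mapRow$flank_right
  off <- rep(NA_integer_, length(positions))
  inL <- positions <= mapRow$left_exon_end &
    positions > mapRow$left_exon_end - fl
  inR <- positions >= mapRow$right_exon_start &
    positions < mapRow$right_exon_start + fr
  off[inL] <- fl - (mapRow$left_exon_end - positions[inL])
  off[inR] <- fl + (positions[inR] - mapRow$right_exon_start) + 1L
  off
}

#' Lift a junction-contig alignment to a split genomic alignment
#'
#' The alignment must span the junction midpoint; alignments entirely inside
#' one flank are rejected (they duplicate the read's genomic hit because the
#' flank length is one base shorter than the read). The lifted alignment
#' carries an N-gap CIGAR between the two exonic blocks.
#'
#' @param contigStart,contigEnd 1-based alignment interval on the contig.
#' @param mapRow One row of \code{junctionMap()} for that contig.
#' @return A list: \code{chrom}, \code{start}, \code{end}, \code{cigar},
#'   \code{blocks} (data.frame of the two genomic blocks with their query
#'   ranges), \code{source = "junction"}.
#' @examples
#' m <- data.frame(chrom = "chr1", left_exon_end = 1000L,
#'                 right_exon_start = 2000L, flank_left = 89L,
#'                 flank_right = 89L)
#' liftJunctionAlignment(85, 94, m)$cigar  # "5M999N5M"
#' @export
liftJunctionAlignment <- function(contigStart, contigEnd, mapRow) {
  fl <- mapRow$flank_left
  stopifnot(contigStart >= 1L, contigEnd >= contigStart,
            contigEnd <= fl + mapRow$flank_right)
  if (contigEnd <= fl || contigStart > fl)
    stop("alignment does not span the junction; redundant with genomic hit")
  leftLen <- fl - contigStart + 1L
  rightLen <- contigEnd - fl
  gap <- mapRow$right_exon_start - mapRow$left_exon_end - 1L
  gstart <- mapRow$left_exon_end - leftLen + 1L
  gend <- mapRow$right_exon_start + rightLen - 1L
  cigar <- if (gap > 0L) {
    sprintf("%dM%dN%dM", leftLen, gap, rightLen)
  } else {
    sprintf("%dM", leftLen + rightLen)
  }
  blocks <- data.frame(
    gstart = c(gstart, mapRow$right_exon_start),
    gend = c(mapRow$left_exon_end, gend),
    qstart = c(1L, leftLen + 1L),
    qend = c(leftLen, leftLen + rightLen))
  list(chrom = mapRow$chrom, start = gstart, end = gend, cigar = cigar,
       blocks = blocks, source = "junction")
}

#' Write a junction library to disk
#'
#' Writes the contigs as FASTA and the lift-over map as TSV.
#'
#' @param jlib A \linkS4class{JunctionLibrary}.
#' @param prefix Output path prefix; writes \code{<prefix>.fa} and
#'   \code{<prefix>.junctions.tsv}.
#' @return Invisibly, the two paths written.
#' @export
writeJunctionLibrary <- function(jlib, prefix) {
  stopifnot(is(jlib, "JunctionLibrary"))
  fa <- paste0(prefix, ".fa")
  tsv <- paste0(prefix, ".junctions.tsv")
  Biostrings::writeXStringSet(jlib@contigs, fa)
  write.table(jlib@map, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fa, tsv))
}
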