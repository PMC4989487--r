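## Per-sample pipeline orchestration, the cross-sample editable-position
## map, liberal retrieval, and the merged output table.

#' Run the full single-sample pipeline
#'
#' Reads and filters the DNA and RNA alignments, builds the quality-filtered
#' pileups, detects candidates, calls genotypes, applies the complete filter
#' cascade (including realignment and the binomial/FDR test) and annotates
#' the result. Deterministic for fixed inputs and config.
#'
#' @param sr A \linkS4class{SampleRun}.
#' @param emitAll Forwarded to \code{\link{detectCandidates}}.
#' @return A list: \code{sample_id}, \code{table} (per-site result
#'   data.frame with all verdicts, sorted by chrom/pos), \code{dnaObs},
#'   \code{rnaObs}, \code{rnaReads}, \code{meanDnaDepth}, \code{genome},
#'   \code{features}, \code{cfg}, \code{library}.
#' @export
runSingleSample <- function(sr, emitAll = FALSE) {
  stopifnot(is(sr, "SampleRun"))
  for (f in c(sr@dnaBam, sr@rnaBam, sr@genomeFasta))
    if (!file.exists(f)) stop("unreadable input: ", f)
  if (nzchar(sr@geneModels) && !file.exists(sr@geneModels))
    stop("unreadable input: ", sr@geneModels)
  if (nzchar(sr@knownSnps) && !file.exists(sr@knownSnps))
    stop("unreadable input: ", sr@knownSnps)
  cfg <- sr@config
  genome <- loadGenome(sr@genomeFasta)
  features <- if (nzchar(sr@geneModels)) buildFeatureIndex(sr@geneModels)
              else NULL
  knownSnps <- if (nzchar(sr@knownSnps)) readKnownSnps(sr@knownSnps)
               else NULL

  dnaReads <- filterReads(readAlignments(sr@dnaBam), cfg@mapqFloor)
  rnaReads <- filterReads(readAlignments(sr@rnaBam), cfg@mapqFloor)
  dnaObs <- pileupObservations(dnaReads, genome,
                               minBaseQual = cfg@minDnaBaseQual,
                               clipN = cfg@clipN)
  rnaObs <- pileupObservations(rnaReads, genome,
                               minBaseQual = cfg@minBaseQual,
                               clipN = cfg@clipN)
  meanDepth <- meanCoveredDepth(dnaObs)

  cand <- detectCandidates(rnaObs, genome, cfg, emitAll = emitAll)
  cand <- applyFilterCascade(cand, list(
    genome = genome, dnaObs = dnaObs, features = features,
    knownSnps = knownSnps, meanDnaDepth = meanDepth, reads = rnaReads,
    cfg = cfg))

  if (nrow(cand)) {
    cand$strand <- vapply(seq_len(nrow(cand)), function(i) {
      gs <- character(0)
      if (!is.null(features)) {
        ann <- annotateSite(cand$chrom[i], cand$pos[i], features)
        hitTx <- ann$transcript_id[!is.na(ann$transcript_id)]
        if (length(hitTx))
          gs <- as.character(GenomicRanges::strand(
            features[features$transcript_id %in% hitTx]))
      }
      inferTranscriptStrand(cand$support_obs[[i]], sr@library,
                            geneStrand = gs)
    }, character(1))
    cand$edit_type <- vapply(seq_len(nrow(cand)), function(i) {
      inferEditType(cand$ref_base[i], cand$alt_base[i], cand$strand[i])
    }, character(1))
    if (!is.null(features))
      cand <- annotateSites(cand, features, genome)
  } else {
    cand$strand <- character(0)
    cand$edit_type <- character(0)
  }
  attrition <- if (nrow(cand)) {
    vapply(CASCADE_FILTERS, function(f) sum(!cand[[f]], na.rm = TRUE),
           integer(1))
  } else {
    stats::setNames(integer(length(CASCADE_FILTERS)), CASCADE_FILTERS)
  }
  message(sprintf("[%s] %d candidates, %d pass; failures per filter: %s",
                  sr@sampleId, nrow(cand), sum(cand$pass),
                  paste(names(attrition), attrition, sep = "=",
                        collapse = " ")))
  list(sample_id = sr@sampleId, table = cand, dnaObs = dnaObs,
       rnaObs = rnaObs, rnaReads = rnaReads, meanDnaDepth = meanDepth,
       genome = genome, features = features, cfg = cfg,
       library = sr@library)
}

#' Read a known-SNP list
#'
#' Accepts a VCF (positions only are used) or a headerless 3-column TSV
#' (chrom, pos, ref).
#'
#' @param path Input path; files ending in .vcf are parsed as VCF.
#' @return A data.frame with columns \code{chrom}, \code{pos}, \code{ref}.
#' @export
readKnownSnps <- function(path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    if (!length(ln))
      return(data.frame(chrom = character(), pos = integer(),
                        ref = character(), stringsAsFactors = FALSE))
    f <- strsplit(ln, "\t")
    return(data.frame(chrom = vapply(f, `[`, "", 1L),
                      pos = as.integer(vapply(f, `[`, "", 2L)),
                      ref = vapply(f, `[`, "", 4L),
                      stringsAsFactors = FALSE))
  }
  tab <- read.table(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  data.frame(chrom = as.character(tab[[1]]), pos = as.integer(tab[[2]]),
             ref = if (ncol(tab) >= 3) as.character(tab[[3]])
                   else NA_character_,
             stringsAsFactors = FALSE)
}

#' Build the cross-sample editable-position map
#'
#' Takes the union of sites passing the full cascade in at least one sample,
#' then discards any position whose genomic DNA is not reliably homozygous
#' in every sample (re-called from each sample's DNA pileup). Uniqueness and
#' splice-distance properties are inherited from the discovery-time verdicts.
#'
#' @param results List of \code{\link{runSingleSample}} results (>= 2).
#' @return A data.frame of editable positions: \code{chrom}, \code{pos},
#'   \code{strand}, \code{ref_base}, \code{alt_base}, \code{edit_type},
#'   \code{discovered_in} (comma-joined sample ids).
#' @export
buildEditablePositions <- function(results) {
  stopifnot(length(results) >= 2L)
  gens <- vapply(results, function(r) {
    paste(names(r$genome), Biostrings::width(r$genome), collapse = ";")
  }, character(1))
  if (length(unique(gens)) != 1L)
    stop("inconsistent genomes across samples")
  passTabs <- lapply(results, function(r) {
    t <- r$table[r$table$pass, c("chrom", "pos", "strand", "ref_base",
                                 "alt_base", "edit_type"), drop = FALSE]
    if (nrow(t)) t$sample <- r$sample_id
    t
  })
  u <- do.call(rbind, passTabs)
  if (is.null(u) || !nrow(u)) {
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), ref_base = character(),
                      alt_base = character(), edit_type = character(),
                      discovered_in = character(), stringsAsFactors = FALSE)
    return(out)
  }
  key <- paste(u$chrom, u$pos, u$strand, u$alt_base)
  agg <- u[!duplicated(key), c("chrom", "pos", "strand", "ref_base",
                               "alt_base", "edit_type"), drop = FALSE]
  agg$discovered_in <- vapply(split(u$sample, key)[unique(key)],
                              function(s) paste(sort(unique(s)),
                                                collapse = ","),
                              character(1))
  ## the genomic DNA must be homozygous in every sample
  homAll <- vapply(seq_len(nrow(agg)), function(i) {
    all(vapply(results, function(r) {
      so <- siteObservationsAt(r$dnaObs, emptyPileupTable(), r$genome,
                               agg$chrom[i], agg$pos[i])
      callPasses(callGenotype(so, r$cfg))
    }, logical(1)))
  }, logical(1))
  agg <- agg[homAll, , drop = FALSE]
  agg <- agg[order(agg$chrom, agg$pos, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Retrieve editing signals at editable positions in one sample
#'
#' Re-queries each editable position under the liberal criteria: at least
#' one supporting RNA read and a BH FDR (recomputed per sample over exactly
#' the queried set) at or below the cutoff. Counts are reported even when a
#' position fails the liberal criteria.
#'
#' @param positions Editable positions from
#'   \code{\link{buildEditablePositions}}.
#' @param result One \code{\link{runSingleSample}} result.
#' @param fdrCutoff FDR cutoff for retrieval (default: the sample config's).
#' @return A data.frame per position: \code{n_total}, \code{k_edited},
#'   \code{editing_level}, \code{p_value}, \code{q_value}, \code{status}
#'   ("discovered", "retrieved" or "absent").
#' @export
retrieveInSample <- function(positions, result, fdrCutoff = NULL) {
  cfg <- result$cfg
  if (is.null(fdrCutoff)) fdrCutoff <- cfg@fdrCutoff
  n <- nrow(positions)
  out <- cbind(positions,
               data.frame(n_total = integer(n), k_edited = integer(n),
                          editing_level = numeric(n),
                          p_value = rep(NA_real_, n),
                          q_value = rep(NA_real_, n),
                          status = rep("absent", n),
                          stringsAsFactors = FALSE))
  if (!n) return(out)
  obs <- result$rnaObs
  fp <- paste(obs$read_start, obs$read_end, obs$read_strand, obs$mate)
  okey <- paste(obs$chrom, obs$pos)
  for (i in seq_len(n)) {
    sel <- okey == paste(positions$chrom[i], positions$pos[i])
    so <- obs[sel, , drop = FALSE]
    sfp <- fp[sel]
    keep <- !duplicated(sfp)
    so <- so[keep, , drop = FALSE]
    out$n_total[i] <- nrow(so)
    out$k_edited[i] <- sum(so$base == positions$alt_base[i])
    out$editing_level[i] <- if (nrow(so)) out$k_edited[i] / nrow(so) else 0
  }
  measurable <- out$n_total > 0L
  out$p_value[measurable] <- binomErrorTest(out$k_edited[measurable],
                                            out$n_total[measurable],
                                            errRate(cfg))
  out$q_value[measurable] <- bhFdr(out$p_value[measurable])
  retrieved <- measurable & out$k_edited >= 1L & out$q_value <= fdrCutoff
  out$status[retrieved] <- "retrieved"
  disc <- result$table[result$table$pass, , drop = FALSE]
  if (nrow(disc)) {
    dkey <- paste(disc$chrom, disc$pos)
    out$status[paste(out$chrom, out$pos) %in% dkey] <- "discovered"
  }
  out
}

#' Merge discovery and retrieval across samples
#'
#' One row per editable position with per-sample column blocks
#' (\code{<id>.n}, \code{<id>.k}, \code{<id>.level}, \code{<id>.q},
#' \code{<id>.status}); rows are ordered by chrom, pos, strand, so two runs
#' with identical inputs produce identical tables.
#'
#' @param positions Editable positions.
#' @param retrievals Named list (by sample id) of
#'   \code{\link{retrieveInSample}} outputs.
#' @return The merged data.frame.
#' @export
mergeOutputs <- function(positions, retrievals) {
  out <- positions
  for (sid in names(retrievals)) {
    r <- retrievals[[sid]]
    stopifnot(nrow(r) == nrow(out))
    out[[paste0(sid, ".n")]] <- r$n_total
    out[[paste0(sid, ".k")]] <- r$k_edited
    out[[paste0(sid, ".level")]] <- r$editing_level
    out[[paste0(sid, ".q")]] <- r$q_value
    out[[paste0(sid, ".status")]] <- r$status
  }
  out <- out[order(out$chrom, out$pos, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the complete multi-sample workflow
#'
#' Runs each sample's discovery pipeline, builds the editable-position map,
#' retrieves each sample at those positions under the liberal criteria and
#' merges everything into one table.
#'
#' @param samples List of \linkS4class{SampleRun} objects (>= 2).
#' @param fdrCutoff Retrieval FDR cutoff (default: each sample's configured
#'   cutoff).
#' @return A list: \code{results} (per-sample pipeline outputs),
#'   \code{positions}, \code{retrievals}, \code{merged}.
#' @export
runMultiSample <- function(samples, fdrCutoff = NULL) {
  results <- lapply(samples, runSingleSample)
  positions <- buildEditablePositions(results)
  retrievals <- lapply(results, retrieveInSample, positions = positions,
                       fdrCutoff = fdrCutoff)
  names(retrievals) <- vapply(results, `[[`, "", "sample_id")
  list(results = results, positions = positions, retrievals = retrievals,
       merged = mergeOutputs(positions, retrievals))
}
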