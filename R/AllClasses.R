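## Central S4 classes. Bulk per-site results travel as plain data.frames
## (one row per site/candidate), in the style of limma/DESeq2 result tables;
## the classes below hold configuration and per-site evidence.

#' FilterConfig: thresholds of the editing-site filter cascade
#'
#' Holds every tunable threshold of the identification pipeline. Defaults are
#' the pipeline's standard operating point: at least three non-redundant
#' supporting RNA reads, editing level at least 5\%, RNA base quality at least
#' Phred 30 (a per-base error ceiling of 0.1\%), DNA depth at least 10 with a
#' homozygosity posterior of at least 0.95, 6-base end clipping, 6-bp splice
#' distance, homopolymer runs of 5 or more discarded, DNA depth capped at
#' twice the genome-wide mean, realignment second-hit ratio 95\% with a
#' qualifying-read fraction that must exceed 50\%, and an FDR cutoff of 0.05.
#'
#' @slot minSupportReads integer, minimum non-redundant supporting RNA reads.
#' @slot minEditingLevel numeric, minimum editing level (fraction).
#' @slot minBaseQual integer, minimum RNA base Phred quality.
#' @slot minDnaBaseQual integer, minimum DNA base Phred quality used in pileup.
#' @slot minDnaDepth integer, minimum DNA read depth for a genotype call.
#' @slot minPosterior numeric, minimum posterior for a homozygous call.
#' @slot clipN integer, bases masked at each read end.
#' @slot spliceDist integer, intronic exclusion distance from splice sites (bp).
#' @slot homopolymerLen integer, minimal homopolymer run length discarded.
#' @slot depthCapFactor numeric, DNA depth cap as a multiple of the genome mean.
#' @slot secondHitRatio numeric, realignment second-best/best score ratio.
#' @slot qualifyFraction numeric, minimal fraction of qualifying reads (strict).
#' @slot fdrCutoff numeric, BH FDR cutoff.
#' @slot errRate numeric, per-base error used by the binomial editing test;
#'   \code{NA} means derive it from \code{minBaseQual} as \code{10^(-q/10)}.
#' @slot genotypeModel character, one of "bayes", "binomial", "frequency".
#' @slot ploidy integer, sample ploidy (2 for one diploid, 2m for m pooled).
#' @slot maxAltFreq numeric, frequency-model alternative-allele ceiling.
#' @slot mapqFloor integer, mapping-quality fallback when uniqueness tags are
#'   absent.
#' @export
setClass("FilterConfig", representation(
  minSupportReads = "integer",
  minEditingLevel = "numeric",
  minBaseQual     = "integer",
  minDnaBaseQual  = "integer",
  minDnaDepth     = "integer",
  minPosterior    = "numeric",
  clipN           = "integer",
  spliceDist      = "integer",
  homopolymerLen  = "integer",
  depthCapFactor  = "numeric",
  secondHitRatio  = "numeric",
  qualifyFraction = "numeric",
  fdrCutoff       = "numeric",
  errRate         = "numeric",
  genotypeModel   = "character",
  ploidy          = "integer",
  maxAltFreq      = "numeric",
  mapqFloor       = "integer"
))

setValidity("FilterConfig", function(object) {
  msg <- character()
  pos <- c(minSupportReads = object@minSupportReads,
           minDnaDepth = object@minDnaDepth,
           spliceDist = object@spliceDist,
           homopolymerLen = object@homopolymerLen,
           depthCapFactor = object@depthCapFactor,
           secondHitRatio = object@secondHitRatio,
           qualifyFraction = object@qualifyFraction,
           fdrCutoff = object@fdrCutoff)
  if (any(pos <= 0))
    msg <- c(msg, paste("thresholds must be positive:",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  frac <- c(minEditingLevel = object@minEditingLevel,
            secondHitRatio = object@secondHitRatio,
            qualifyFraction = object@qualifyFraction,
            fdrCutoff = object@fdrCutoff,
            minPosterior = object@minPosterior)
  if (any(frac <= 0 | frac > 1))
    msg <- c(msg, "fractional thresholds must lie in (0, 1]")
  if (!object@genotypeModel %in% c("bayes", "binomial", "frequency"))
    msg <- c(msg, "genotypeModel must be 'bayes', 'binomial' or 'frequency'")
  if (object@ploidy < 1L) msg <- c(msg, "ploidy must be >= 1")
  if (object@maxAltFreq < 0 || object@maxAltFreq >= 1)
    msg <- c(msg, "maxAltFreq must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a FilterConfig
#'
#' @param minSupportReads,minEditingLevel,minBaseQual,minDnaBaseQual,minDnaDepth
#'   Support/level/quality/depth thresholds; see the class documentation.
#' @param minPosterior,clipN,spliceDist,homopolymerLen,depthCapFactor
#'   Genotype and positional filter thresholds.
#' @param secondHitRatio,qualifyFraction Realignment-filter thresholds.
#' @param fdrCutoff,errRate Binomial test FDR cutoff and error rate
#'   (\code{NA} derives the rate from \code{minBaseQual}).
#' @param genotypeModel,ploidy,maxAltFreq,mapqFloor Genotype model selection
#'   and read-uniqueness fallback.
#' @return A validated \linkS4class{FilterConfig}.
#' @examples
#' cfg <- filterConfig()
#' errRate(cfg)  # 0.001, from the Phred-30 default
#' @export
filterConfig <- function(minSupportReads = 3L, minEditingLevel = 0.05,
                         minBaseQual = 30L, minDnaBaseQual = 20L,
                         minDnaDepth = 10L, minPosterior = 0.95,
                         clipN = 6L, spliceDist = 6L, homopolymerLen = 5L,
                         depthCapFactor = 2.0, secondHitRatio = 0.95,
                         qualifyFraction = 0.50, fdrCutoff = 0.05,
                         errRate = NA_real_, genotypeModel = "bayes",
                         ploidy = 2L, maxAltFreq = 0, mapqFloor = 20L) {
  new("FilterConfig",
      minSupportReads = as.integer(minSupportReads),
      minEditingLevel = minEditingLevel,
      minBaseQual = as.integer(minBaseQual),
      minDnaBaseQual = as.integer(minDnaBaseQual),
      minDnaDepth = as.integer(minDnaDepth),
      minPosterior = minPosterior,
      clipN = as.integer(clipN),
      spliceDist = as.integer(spliceDist),
      homopolymerLen = as.integer(homopolymerLen),
      depthCapFactor = depthCapFactor,
      secondHitRatio = secondHitRatio,
      qualifyFraction = qualifyFraction,
      fdrCutoff = fdrCutoff,
      errRate = errRate,
      genotypeModel = genotypeModel,
      ploidy = as.integer(ploidy),
      maxAltFreq = maxAltFreq,
      mapqFloor = as.integer(mapqFloor))
}

#' Effective per-base error rate of a FilterConfig
#'
#' @param x A \linkS4class{FilterConfig}.
#' @return The configured binomial-test error rate, or
#'   \code{10^(-minBaseQual/10)} when unset.
#' @export
errRate <- function(x) {
  stopifnot(is(x, "FilterConfig"))
  if (is.na(x@errRate)) phredToError(x@minBaseQual) else x@errRate
}

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat("  support >=", object@minSupportReads,
      "| level >=", object@minEditingLevel,
      "| RNA qual >=", object@minBaseQual, "\n")
  cat("  DNA depth >=", object@minDnaDepth,
      "| posterior >=", object@minPosterior,
      "| model:", object@genotypeModel,
      "| ploidy:", object@ploidy, "\n")
  cat("  clip:", object@clipN, "| splice dist:", object@spliceDist,
      "| homopolymer >=", object@homopolymerLen,
      "| depth cap: ", object@depthCapFactor, "x mean\n", sep = "")
  cat("  realign: second <", object@secondHitRatio,
      "x best, qualifying >", object@qualifyFraction,
      "| FDR <=", object@fdrCutoff,
      "| err rate:", signif(errRate(object), 3), "\n")
})

#' JunctionLibrary: splice-junction contigs and their lift-over map
#'
#' A set of artificial contigs, one per distinct splice junction, each built
#' from the exonic flanks on either side of the junction, together with the
#' table needed to convert alignments on those contigs back to genomic
#' coordinates.
#'
#' @slot contigs A \code{DNAStringSet}, one entry per junction, named by
#'   junction id.
#' @slot map A data.frame with columns \code{junction_id}, \code{chrom},
#'   \code{left_exon_end}, \code{right_exon_start}, \code{flank_length},
#'   \code{flank_left}, \code{flank_right}, \code{strand}, \code{short_flank}.
#' @slot readLength The read length the library was built for.
#' @export
setClass("JunctionLibrary", representation(
  contigs = "DNAStringSet",
  map = "data.frame",
  readLength = "integer"
))

setValidity("JunctionLibrary", function(object) {
  m <- object@map
  need <- c("junction_id", "chrom", "left_exon_end", "right_exon_start",
            "flank_length", "flank_left", "flank_right", "strand",
            "short_flank")
  if (!all(need %in% names(m)))
    return(paste("map lacks columns:",
                 paste(setdiff(need, names(m)), collapse = ", ")))
  if (length(object@contigs) != nrow(m))
    return("one contig per map row required")
  if (nrow(m)) {
    if (any(m$right_exon_start <= m$left_exon_end))
      return("right_exon_start must exceed left_exon_end")
    if (any(m$flank_length < 1L)) return("flank_length must be >= 1")
    if (any(Biostrings::width(object@contigs) != m$flank_left + m$flank_right))
      return("contig length must equal flank_left + flank_right")
  }
  TRUE
})

setMethod("show", "JunctionLibrary", function(object) {
  cat("JunctionLibrary:", length(object@contigs), "junctions, read length",
      object@readLength, "(flank", object@readLength - 1L, "bp)\n")
  if (any(object@map$short_flank))
    cat(" ", sum(object@map$short_flank), "junction(s) with truncated flanks\n")
})

#' Junction map accessor
#' @param x A \linkS4class{JunctionLibrary}.
#' @return The lift-over data.frame.
#' @export
junctionMap <- function(x) { stopifnot(is(x, "JunctionLibrary")); x@map }

#' Junction contig accessor
#' @param x A \linkS4class{JunctionLibrary}.
#' @return The junction contigs as a \code{DNAStringSet}.
#' @export
junctionContigs <- function(x) { stopifnot(is(x, "JunctionLibrary")); x@contigs }

#' SiteObservations: the DNA and RNA base stacks at one genomic site
#'
#' @slot chrom Chromosome name.
#' @slot pos 1-based genomic position.
#' @slot refBase Reference base at the position.
#' @slot dna data.frame of DNA base observations (columns \code{base},
#'   \code{qual}, \code{rid}, \code{read_pos}, \code{read_len},
#'   \code{read_start}, \code{read_end}, \code{read_strand}, \code{mate}).
#' @slot rna data.frame of RNA base observations, same columns.
#' @export
setClass("SiteObservations", representation(
  chrom = "character", pos = "integer", refBase = "character",
  dna = "data.frame", rna = "data.frame"
))

setValidity("SiteObservations", function(object) {
  if (!object@refBase %in% BASES) return("refBase must be one of A/C/G/T")
  for (layer in list(object@dna, object@rna)) {
    if (nrow(layer) && !all(layer$base %in% BASES))
      return("observations must be A/C/G/T (N is dropped at pileup)")
  }
  TRUE
})

setMethod("show", "SiteObservations", function(object) {
  cat(sprintf("SiteObservations %s:%d ref=%s  DNA depth %d, RNA depth %d\n",
              object@chrom, object@pos, object@refBase,
              nrow(object@dna), nrow(object@rna)))
})

#' Construct a SiteObservations object
#'
#' @param chrom,pos,refBase Site coordinates and reference base.
#' @param dna,rna Observation data.frames; minimally columns \code{base} and
#'   \code{qual}. Missing read-metadata columns are filled with defaults so
#'   that small hand-built stacks are convenient in examples and tests.
#' @return A \linkS4class{SiteObservations}.
#' @export
siteObservations <- function(chrom, pos, refBase,
                             dna = emptyObsTable(), rna = emptyObsTable()) {
  new("SiteObservations", chrom = as.character(chrom), pos = as.integer(pos),
      refBase = toupper(refBase),
      dna = completeObsTable(dna), rna = completeObsTable(rna))
}

emptyObsTable <- function() {
  data.frame(base = character(), qual = integer(), rid = integer(),
             read_pos = integer(), read_len = integer(),
             read_start = integer(), read_end = integer(),
             read_strand = character(), mate = character(),
             stringsAsFactors = FALSE)
}

completeObsTable <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  n <- nrow(df)
  if (n == 0 && !length(df)) return(emptyObsTable())
  stopifnot(all(c("base", "qual") %in% names(df)))
  fill <- list(rid = seq_len(n), read_pos = 45L, read_len = 90L,
               read_start = NA_integer_, read_end = NA_integer_,
               read_strand = "+", mate = "single")
  for (nm in names(fill))
    if (is.null(df[[nm]])) df[[nm]] <- rep(fill[[nm]], length.out = n)
  df$base <- toupper(df$base)
  df
}

#' Convenience builder for a base stack
#'
#' Expands a named count vector like \code{c(A = 18, G = 2)} into an
#' observation table at a single quality.
#'
#' @param counts Named integer vector over A/C/G/T.
#' @param qual Phred quality assigned to every observation.
#' @return Observation data.frame suitable for \code{\link{siteObservations}}.
#' @export
baseStack <- function(counts, qual = 40L) {
  base <- rep(names(counts), counts)
  completeObsTable(data.frame(base = base, qual = as.integer(qual),
                              stringsAsFactors = FALSE))
}

#' GenotypeCall: the homozygosity verdict for one site
#'
#' @slot chrom,pos Site coordinates.
#' @slot model Calling model used: "bayes", "binomial" or "frequency".
#' @slot genotype Best genotype as a sorted allele string (e.g. "AA", "AG",
#'   "AAAG" at ploidy 4).
#' @slot score Posterior probability (bayes), upper-tail probability
#'   (binomial) or alternative-allele frequency (frequency).
#' @slot dnaDepth DNA read depth used.
#' @slot isHomozygous Whether the best genotype carries a single allele.
#' @slot passes Whether the site passes the homozygosity gate (homozygous,
#'   score threshold and depth threshold all satisfied).
#' @slot baseCounts Named integer vector of DNA base counts.
#' @export
setClass("GenotypeCall", representation(
  chrom = "character", pos = "integer", model = "character",
  genotype = "character", score = "numeric", dnaDepth = "integer",
  isHomozygous = "logical", passes = "logical", baseCounts = "integer"
))

setValidity("GenotypeCall", function(object) {
  if (!object@model %in% c("bayes", "binomial", "frequency"))
    return("model must be 'bayes', 'binomial' or 'frequency'")
  if (object@passes && !object@isHomozygous)
    return("passes implies isHomozygous")
  if (object@model == "bayes" && !is.na(object@score) &&
      (object@score < 0 || object@score > 1))
    return("bayes posterior must lie in [0, 1]")
  TRUE
})

setMethod("show", "GenotypeCall", function(object) {
  cat(sprintf(
    "GenotypeCall %s:%d [%s] %s score=%.4g depth=%d hom=%s passes=%s\n",
    object@chrom, object@pos, object@model, object@genotype, object@score,
    object@dnaDepth, object@isHomozygous, object@passes))
})

#' @rdname genotypeAccessors
#' @name genotypeAccessors
#' @title Accessors for GenotypeCall
#' @param x A \linkS4class{GenotypeCall}.
#' @return \code{calledGenotype}: the allele string; \code{callScore}: the
#'   posterior/score; \code{isHomozygous}/\code{callPasses}: logicals;
#'   \code{dnaDepth}: integer depth.
NULL

#' @rdname genotypeAccessors
#' @export
calledGenotype <- function(x) { stopifnot(is(x, "GenotypeCall")); x@genotype }
#' @rdname genotypeAccessors
#' @export
callScore <- function(x) { stopifnot(is(x, "GenotypeCall")); x@score }
#' @rdname genotypeAccessors
#' @export
isHomozygous <- function(x) { stopifnot(is(x, "GenotypeCall")); x@isHomozygous }
#' @rdname genotypeAccessors
#' @export
callPasses <- function(x) { stopifnot(is(x, "GenotypeCall")); x@passes }
#' @rdname genotypeAccessors
#' @export
dnaDepth <- function(x) { stopifnot(is(x, "GenotypeCall")); x@dnaDepth }

#' SampleRun: one sample's inputs and configuration
#'
#' @slot sampleId Sample identifier used in merged outputs.
#' @slot dnaBam,rnaBam Paths to coordinate-sorted DNA and RNA alignments
#'   (SAM or BAM).
#' @slot genomeFasta Path to the reference genome FASTA.
#' @slot geneModels Path to the gene models (GTF/GFF3), or "".
#' @slot ploidy Sample ploidy.
#' @slot library "stranded_dUTP" or "unstranded".
#' @slot config The sample's \linkS4class{FilterConfig}.
#' @slot knownSnps Path to a known-SNP list (VCF or 3-column TSV), or "".
#' @export
setClass("SampleRun", representation(
  sampleId = "character", dnaBam = "character", rnaBam = "character",
  genomeFasta = "character", geneModels = "character", ploidy = "integer",
  library = "character", config = "FilterConfig", knownSnps = "character"
))

setValidity("SampleRun", function(object) {
  if (object@ploidy < 1L) return("ploidy must be >= 1")
  if (!object@library %in% c("stranded_dUTP", "unstranded"))
    return("library must be 'stranded_dUTP' or 'unstranded'")
  TRUE
})

#' Construct a SampleRun
#'
#' @param sampleId,dnaBam,rnaBam,genomeFasta,geneModels,knownSnps Paths and
#'   identifier; see the class documentation.
#' @param ploidy Sample ploidy (2 for one diploid individual, 2m for a pool
#'   of m diploids).
#' @param library RNA library type.
#' @param config \linkS4class{FilterConfig} overrides for this sample.
#' @return A validated \linkS4class{SampleRun}.
#' @export
sampleRun <- function(sampleId, dnaBam, rnaBam, genomeFasta,
                      geneModels = "", ploidy = 2L,
                      library = c("stranded_dUTP", "unstranded"),
                      config = filterConfig(ploidy = ploidy),
                      knownSnps = "") {
  library <- match.arg(library)
  new("SampleRun", sampleId = sampleId, dnaBam = dnaBam, rnaBam = rnaBam,
      genomeFasta = genomeFasta, geneModels = geneModels,
      ploidy = as.integer(ploidy), library = library, config = config,
      knownSnps = knownSnps)
}

setMethod("show", "SampleRun", function(object) {
  cat("SampleRun", object@sampleId, "(ploidy", object@ploidy, ",",
      object@library, ")\n")
  cat("  DNA:", object@dnaBam, "\n  RNA:", object@rnaBam, "\n")
})

#' SimConfig: parameters of the synthetic-data generator
#'
#' The defaults define the standard validation regime: a 50-kb genome with 10
#' multi-exon genes, diploid, heterozygous SNPs at 1 per kb, 50 editing sites
#' with levels drawn uniformly between 0.1 and 0.9, 30x DNA and 50x RNA
#' coverage of 90-bp reads at mean Phred 35, and a 5\% PCR-duplicate rate.
#'
#' @slot seed RNG seed; a fixed seed makes the fixture byte-reproducible.
#' @slot genomeLen Genome length (bp).
#' @slot nGenes Number of multi-exon genes.
#' @slot ploidy Sample ploidy.
#' @slot hetSnpRate Per-bp heterozygous SNP rate.
#' @slot nEditSites Number of planted editing sites.
#' @slot editLevelMin,editLevelMax True editing levels are drawn uniformly
#'   from this range; set both equal for a fixed level.
#' @slot dnaDepth,rnaDepth Mean coverages.
#' @slot readLen Read length (bp).
#' @slot qualMean,qualSd Per-base Phred quality profile.
#' @slot dupRate PCR-duplicate fraction.
#' @slot paralogIdentity,paralogLen Optional paralogous decoy: sequence
#'   identity (0 disables) and copied length (bp).
#' @export
setClass("SimConfig", representation(
  seed = "integer", genomeLen = "integer", nGenes = "integer",
  ploidy = "integer", hetSnpRate = "numeric", nEditSites = "integer",
  editLevelMin = "numeric", editLevelMax = "numeric",
  dnaDepth = "numeric", rnaDepth = "numeric", readLen = "integer",
  qualMean = "numeric", qualSd = "numeric", dupRate = "numeric",
  paralogIdentity = "numeric", paralogLen = "integer"
))

setValidity("SimConfig", function(object) {
  rates <- c(object@hetSnpRate, object@dupRate, object@editLevelMin,
             object@editLevelMax)
  if (any(rates < 0 | rates > 1)) return("rates and levels must lie in [0,1]")
  if (object@editLevelMin > object@editLevelMax)
    return("editLevelMin must not exceed editLevelMax")
  if (object@dnaDepth <= 0 || object@rnaDepth <= 0)
    return("depths must be positive")
  if (object@genomeLen < 10L * object@readLen)
    return("genomeLen must be at least 10 read lengths")
  if (object@paralogIdentity != 0 &&
      (object@paralogIdentity < 0.5 || object@paralogIdentity > 1))
    return("paralogIdentity must be 0 (off) or in [0.5, 1]")
  TRUE
})

#' Construct a SimConfig
#'
#' @param seed,genomeLen,nGenes,ploidy,hetSnpRate,nEditSites Genome and truth
#'   parameters; see the class documentation.
#' @param editLevelMin,editLevelMax Range of true editing levels.
#' @param dnaDepth,rnaDepth,readLen,qualMean,qualSd,dupRate Sequencing
#'   parameters.
#' @param paralogIdentity,paralogLen Paralogous decoy parameters
#'   (identity 0 disables the decoy).
#' @return A validated \linkS4class{SimConfig}.
#' @export
simConfig <- function(seed = 1L, genomeLen = 50000L, nGenes = 10L,
                      ploidy = 2L, hetSnpRate = 0.001, nEditSites = 50L,
                      editLevelMin = 0.1, editLevelMax = 0.9,
                      dnaDepth = 30, rnaDepth = 50, readLen = 90L,
                      qualMean = 35, qualSd = 3, dupRate = 0.05,
                      paralogIdentity = 0, paralogLen = 500L) {
  new("SimConfig", seed = as.integer(seed), genomeLen = as.integer(genomeLen),
      nGenes = as.integer(nGenes), ploidy = as.integer(ploidy),
      hetSnpRate = hetSnpRate, nEditSites = as.integer(nEditSites),
      editLevelMin = editLevelMin, editLevelMax = editLevelMax,
      dnaDepth = dnaDepth, rnaDepth = rnaDepth, readLen = as.integer(readLen),
      qualMean = qualMean, qualSd = qualSd, dupRate = dupRate,
      paralogIdentity = paralogIdentity, paralogLen = as.integer(paralogLen))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(
    "SimConfig: %d bp, %d genes, ploidy %d, %d edits (levels %.2f-%.2f)\n",
    object@genomeLen, object@nGenes, object@ploidy, object@nEditSites,
    object@editLevelMin, object@editLevelMax))
  cat(sprintf("  DNA %gx / RNA %gx, %d-bp reads, Q%g+/-%g, dup %.0f%%\n",
              object@dnaDepth, object@rnaDepth, object@readLen,
              object@qualMean, object@qualSd, 100 * object@dupRate))
  if (object@paralogIdentity > 0)
    cat(sprintf("  paralog decoy: %d bp at %.0f%% identity\n",
                object@paralogLen, 100 * object@paralogIdentity))
})
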