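## Homozygous genotype calling from DNA-seq pileups.
##
## An RNA/DNA mismatch can only be called editing when the genomic DNA is
## reliably homozygous; three interchangeable models decide that, for any
## ploidy (a pool of m diploid individuals behaves as ploidy 2m).

#' Enumerate the genotype space for a given ploidy
#'
#' The space consists of the 4 homozygous genotypes plus, for each of the 6
#' unordered base pairs, every biallelic composition (1..ploidy-1 copies of
#' the first allele), giving 6p - 2 genotypes: 10 at ploidy 2, 22 at ploidy 4.
#' Genotypes with more than two distinct alleles are not considered.
#'
#' @param ploidy Integer >= 1.
#' @return Character vector of sorted allele strings in canonical
#'   (lexicographic) order, e.g. \code{"AA", "AC", ..., "TT"} at ploidy 2.
#' @examples
#' length(enumerateGenotypes(2))  # 10
#' length(enumerateGenotypes(4))  # 22
#' @export
enumerateGenotypes <- function(ploidy) {
  ploidy <- as.integer(ploidy)
  if (is.na(ploidy) || ploidy < 1L) stop("ploidy must be an integer >= 1")
  homo <- vapply(BASES, function(b) strrep(b, ploidy), character(1))
  if (ploidy == 1L) return(sort(unname(homo)))
  pairs <- utils::combn(BASES, 2)
  het <- character(0)
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    for (i in seq_len(ploidy - 1L))
      het <- c(het, paste0(strrep(a, i), strrep(b, ploidy - i)))
  }
  sort(unname(c(homo, het)))
}

genotypeAlleleMatrix <- function(genotypes) {
  ## counts of each base per genotype, rows = genotypes, cols = A/C/G/T
  t(vapply(strsplit(genotypes, ""), function(al) {
    tab <- table(factor(al, levels = BASES))
    as.integer(tab)
  }, integer(4)))
}

#' Log-likelihood of a genotype given base observations
#'
#' For each observed base b with error probability e = 10^(-qual/10), the
#' per-base likelihood under genotype g with ploidy p is
#' sum over alleles a in g of (count_g(a)/p) * ((1-e) if a == b else e/3);
#' the site log-likelihood is the sum of per-base logs. Empty input returns 0.
#'
#' @param bases Character vector of observed bases (A/C/G/T).
#' @param quals Phred qualities, same length as \code{bases}.
#' @param genotype Allele string, e.g. "AA" or "AAAG".
#' @return The log-likelihood (a single numeric).
#' @examples
#' genotypeLikelihood(rep("A", 5), rep(40, 5), "AA")  # 5 * log(1 - 1e-4)
#' @export
genotypeLikelihood <- function(bases, quals, genotype) {
  stopifnot(length(bases) == length(quals), all(quals >= 0))
  if (!length(bases)) return(0)
  alleles <- strsplit(genotype, "")[[1]]
  p <- length(alleles)
  cnt <- table(factor(alleles, levels = BASES)) / p
  e <- phredToError(quals)
  lik <- numeric(length(bases))
  for (a in BASES) {
    w <- as.numeric(cnt[[a]])
    if (w == 0) next
    lik <- lik + w * ifelse(bases == a, 1 - e, e / 3)
  }
  sum(log(lik))
}

#' Construct a genotype prior
#'
#' @param kind "uniform" (default) or "hom_het_weighted", where every
#'   genotype with two distinct alleles receives \code{hetWeight} times the
#'   prior mass of a homozygous genotype.
#' @param hetWeight Relative heterozygote prior mass (default 0.001).
#' @return A list with the normalized prior over a genotype space, to be
#'   resolved against a ploidy by \code{\link{callBayes}}.
#' @export
genotypePrior <- function(kind = c("uniform", "hom_het_weighted"),
                          hetWeight = 0.001) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hetWeight = hetWeight),
            class = "genotypePrior")
}

resolvePrior <- function(prior, genotypes) {
  if (prior$kind == "uniform") {
    w <- rep(1, length(genotypes))
  } else {
    nd <- vapply(strsplit(genotypes, ""),
                 function(a) length(unique(a)), integer(1))
    w <- ifelse(nd == 1L, 1, prior$hetWeight)
  }
  w / sum(w)
}

majorAllele <- function(counts, refBase) {
  ## modal base; ties broken by reference base, then lexicographically
  mx <- max(counts)
  cand <- names(counts)[counts == mx]
  if (refBase %in% cand) refBase else sort(cand)[1]
}

obsBaseCounts <- function(obs) {
  as.integer(table(factor(obs$base, levels = BASES))) |>
    stats::setNames(BASES)
}

newGenotypeCall <- function(site, model, genotype, score, depth, hom, passes,
                            counts) {
  new("GenotypeCall", chrom = site$chrom, pos = as.integer(site$pos),
      model = model, genotype = genotype, score = score,
      dnaDepth = as.integer(depth), isHomozygous = hom, passes = passes,
      baseCounts = counts)
}

#' Bayesian homozygosity call
#'
#' Computes the posterior probability of every genotype in the ploidy's
#' genotype space from the DNA base stack and reports the maximum-posterior
#' genotype. The site passes when that genotype is homozygous, its posterior
#' reaches \code{minPosterior} and the DNA depth reaches \code{minDepth}.
#'
#' @param site A \linkS4class{SiteObservations}.
#' @param ploidy Sample ploidy.
#' @param prior A \code{\link{genotypePrior}}.
#' @param minPosterior Posterior threshold (0.95 or 0.99 typically).
#' @param minDepth Minimum DNA read depth (default 10).
#' @return A \linkS4class{GenotypeCall} with the posterior as score.
#' @examples
#' so <- siteObservations("chr1", 100, "A", dna = baseStack(c(A = 20)))
#' callBayes(so, ploidy = 2)
#' @export
callBayes <- function(site, ploidy = 2L, prior = genotypePrior(),
                      minPosterior = 0.95, minDepth = 10L) {
  stopifnot(is(site, "SiteObservations"), minPosterior > 0, minPosterior <= 1)
  obs <- site@dna
  counts <- obsBaseCounts(obs)
  depth <- nrow(obs)
  info <- list(chrom = site@chrom, pos = site@pos)
  if (depth == 0L) {
    return(newGenotypeCall(info, "bayes", NA_character_, NA_real_, 0L,
                           FALSE, FALSE, counts))
  }
  post <- genotypePosteriors(obs$base, obs$qual, ploidy, prior)
  best <- which.max(post)  # ties: first in canonical order
  g <- names(post)[best]
  hom <- length(unique(strsplit(g, "")[[1]])) == 1L
  passes <- hom && post[[best]] >= minPosterior && depth >= minDepth
  newGenotypeCall(info, "bayes", g, unname(post[best]), depth, hom, passes,
                  counts)
}

#' Posterior distribution over the genotype space
#'
#' @param bases,quals Observed DNA bases and Phred qualities.
#' @param ploidy Sample ploidy.
#' @param prior A \code{\link{genotypePrior}}.
#' @return Named numeric vector of posterior probabilities (sums to 1) over
#'   \code{enumerateGenotypes(ploidy)}.
#' @export
genotypePosteriors <- function(bases, quals, ploidy = 2L,
                               prior = genotypePrior()) {
  gts <- enumerateGenotypes(ploidy)
  pw <- resolvePrior(prior, gts)
  ll <- vapply(gts, function(g) genotypeLikelihood(bases, quals, g),
               numeric(1))
  lp <- ll + log(pw)
  stats::setNames(exp(lp - logSumExp(lp)), gts)
}

#' Binomial homozygosity call
#'
#' Tests whether the minor-allele count is consistent with sequencing error:
#' with n = DNA depth and k = non-major-allele count, computes the upper-tail
#' probability P(X >= k) for X ~ Binomial(n, errorRate). The site is deemed
#' homozygous for the major allele when that probability is >= alpha (the
#' observed minor bases are explainable as errors).
#'
#' @param site A \linkS4class{SiteObservations}.
#' @param ploidy Sample ploidy (determines the reported allele string).
#' @param errorRate Per-base error; \code{NULL} (default) uses the mean of the
#'   per-base error probabilities of the DNA observations, floored at 1e-4.
#' @param alpha Significance level (default 0.05).
#' @param minDepth Minimum DNA depth.
#' @return A \linkS4class{GenotypeCall} with the tail probability as score.
#' @export
callBinomial <- function(site, ploidy = 2L, errorRate = NULL, alpha = 0.05,
                         minDepth = 10L) {
  stopifnot(is(site, "SiteObservations"))
  obs <- site@dna
  counts <- obsBaseCounts(obs)
  depth <- nrow(obs)
  info <- list(chrom = site@chrom, pos = site@pos)
  if (depth == 0L) {
    return(newGenotypeCall(info, "binomial", NA_character_, NA_real_, 0L,
                           FALSE, FALSE, counts))
  }
  if (is.null(errorRate))
    errorRate <- max(mean(phredToError(obs$qual)), 1e-4)
  stopifnot(errorRate > 0, errorRate < 1)
  major <- majorAllele(counts, site@refBase)
  k <- depth - counts[[major]]
  pval <- pbinom(k - 1L, depth, errorRate, lower.tail = FALSE)
  hom <- pval >= alpha
  g <- if (hom) strrep(major, ploidy) else NA_character_
  passes <- hom && depth >= minDepth
  newGenotypeCall(info, "binomial", g, pval, depth, hom, passes, counts)
}

#' Frequency-model homozygosity call
#'
#' Declares a site homozygous when the non-major-allele fraction of the DNA
#' base stack does not exceed \code{maxAltFreq} (default 0, the strictest
#' reading: no alternative bases tolerated).
#'
#' @param site A \linkS4class{SiteObservations}.
#' @param ploidy Sample ploidy (determines the reported allele string).
#' @param maxAltFreq Maximum tolerated alternative-allele fraction.
#' @param minDepth Minimum DNA depth.
#' @return A \linkS4class{GenotypeCall} with the alternative fraction as score.
#' @export
callFrequency <- function(site, ploidy = 2L, maxAltFreq = 0,
                          minDepth = 10L) {
  stopifnot(is(site, "SiteObservations"), maxAltFreq >= 0, maxAltFreq < 1)
  obs <- site@dna
  counts <- obsBaseCounts(obs)
  depth <- nrow(obs)
  info <- list(chrom = site@chrom, pos = site@pos)
  if (depth == 0L) {
    return(newGenotypeCall(info, "frequency", NA_character_, NA_real_, 0L,
                           FALSE, FALSE, counts))
  }
  major <- majorAllele(counts, site@refBase)
  altFreq <- (depth - counts[[major]]) / depth
  hom <- altFreq <= maxAltFreq
  g <- if (hom) strrep(major, ploidy) else NA_character_
  passes <- hom && depth >= minDepth
  newGenotypeCall(info, "frequency", g, altFreq, depth, hom, passes, counts)
}

#' Dispatch a homozygosity call per a FilterConfig
#'
#' @param site A \linkS4class{SiteObservations}.
#' @param cfg A \linkS4class{FilterConfig}; \code{genotypeModel} selects the
#'   model, \code{ploidy}, \code{minPosterior}, \code{minDnaDepth} and
#'   \code{maxAltFreq} parameterize it.
#' @return A \linkS4class{GenotypeCall}.
#' @export
callGenotype <- function(site, cfg = filterConfig()) {
  switch(cfg@genotypeModel,
    bayes = callBayes(site, ploidy = cfg@ploidy,
                      minPosterior = cfg@minPosterior,
                      minDepth = cfg@minDnaDepth),
    binomial = callBinomial(site, ploidy = cfg@ploidy,
                            minDepth = cfg@minDnaDepth),
    frequency = callFrequency(site, ploidy = cfg@ploidy,
                              maxAltFreq = cfg@maxAltFreq,
                              minDepth = cfg@minDnaDepth))
}
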