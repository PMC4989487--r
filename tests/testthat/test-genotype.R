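test_that("genotype space has 6p-2 members and matches brute-force enumeration", {
  expect_equal(length(enumerateGenotypes(1)), 4L)
  expect_equal(length(enumerateGenotypes(2)), 10L)
  expect_equal(enumerateGenotypes(2),
               sort(c("AA", "CC", "GG", "TT", "AC", "AG", "AT", "CG", "CT",
                      "GT")))
  expect_equal(length(enumerateGenotypes(4)), 22L)
  expect_equal(length(enumerateGenotypes(8)), 46L)
  for (p in 1:6) {
    gts <- enumerateGenotypes(p)
    expect_equal(length(gts), 6L * p - 2L)
    expect_setequal(gts, oracleGenotypeSpace(p))
  }
  expect_error(enumerateGenotypes(0), "ploidy")
})

test_that("genotype likelihood matches closed forms", {
  e <- phredToError(40)
  expect_equal(genotypeLikelihood(rep("A", 5), rep(40, 5), "AA"),
               5 * log(1 - e))
  # heterozygote: two-term per-base mixture
  expect_equal(genotypeLikelihood("A", 25, "AG"),
               log(0.5 * (1 - phredToError(25)) + 0.5 * phredToError(25) / 3))
  # error-free limit: matching homozygote likelihood tends to 0
  expect_lt(abs(genotypeLikelihood(rep("C", 10), rep(90, 10), "CC")), 1e-8)
  # empty observations are the identity case
  expect_equal(genotypeLikelihood(character(0), numeric(0), "AA"), 0)
})

test_that("Bayesian caller ranks genotypes correctly and gates on depth", {
  soHom <- siteObservations("chr1", 10, "A", dna = baseStack(c(A = 20)))
  call <- callBayes(soHom, ploidy = 2)
  expect_equal(calledGenotype(call), "AA")
  expect_gt(callScore(call), 0.99)
  expect_true(callPasses(call))

  soHet <- siteObservations("chr1", 11, "A",
                            dna = baseStack(c(A = 5, G = 5)))
  het <- callBayes(soHet, ploidy = 2)
  expect_equal(calledGenotype(het), "AG")
  expect_false(isHomozygous(het))
  expect_false(callPasses(het))

  gated <- callBayes(soHom, ploidy = 2, minDepth = 25)
  expect_true(isHomozygous(gated))
  expect_false(callPasses(gated))

  zero <- callBayes(siteObservations("chr1", 12, "A"), ploidy = 2)
  expect_false(callPasses(zero))
  expect_true(is.na(callScore(zero)))
})

test_that("posteriors sum to one over the genotype space", {
  set.seed(101)
  for (i in 1:50) {
    p <- sample(c(1L, 2L, 4L), 1)
    depth <- sample(1:40, 1)
    bases <- sample(c("A", "C", "G", "T"), depth, replace = TRUE)
    quals <- sample(20:40, depth, replace = TRUE)
    post <- genotypePosteriors(bases, quals, ploidy = p)
    expect_equal(sum(post), 1, tolerance = 1e-9)
    expect_equal(length(post), 6L * p - 2L)
  }
})

test_that("adding a major-allele observation never lowers the homozygous posterior", {
  set.seed(77)
  for (i in 1:20) {
    depth <- sample(5:30, 1)
    bases <- c(rep("A", depth), sample(c("C", "G", "T"), 3, replace = TRUE))
    quals <- sample(25:40, length(bases), replace = TRUE)
    before <- genotypePosteriors(bases, quals)[["AA"]]
    after <- genotypePosteriors(c(bases, "A"), c(quals, 35))[["AA"]]
    expect_gte(after, before - 1e-12)
  }
})

test_that("binomial model separates heterozygotes from error and gates on depth", {
  clean <- callBinomial(
    siteObservations("chr1", 1, "A", dna = baseStack(c(A = 20))),
    errorRate = 0.001)
  expect_equal(callScore(clean), 1)  # k = 0
  expect_true(callPasses(clean))

  het <- callBinomial(
    siteObservations("chr1", 2, "A", dna = baseStack(c(A = 15, G = 5))),
    errorRate = 0.001)
  expect_false(isHomozygous(het))
  expect_equal(callScore(het), oracleBinomTail(5, 20, 0.001),
               tolerance = 1e-12)

  gated <- callBinomial(
    siteObservations("chr1", 3, "A", dna = baseStack(c(A = 10))),
    errorRate = 0.001, minDepth = 11)
  expect_true(isHomozygous(gated))
  expect_false(callPasses(gated))
})

test_that("frequency model applies the alternative-allele ceiling", {
  mk <- function(counts) siteObservations("chr1", 1, "A",
                                          dna = baseStack(counts))
  expect_true(callPasses(callFrequency(mk(c(A = 30)))))
  expect_false(isHomozygous(callFrequency(mk(c(A = 29, G = 1)))))
  expect_true(callPasses(callFrequency(mk(c(A = 48, G = 2)),
                                       maxAltFreq = 0.05)))
})

test_that("the three models agree on clean homozygous sites", {
  set.seed(55)
  n <- 300
  agree <- vapply(seq_len(n), function(i) {
    depth <- sample(20:60, 1)
    so <- siteObservations("chr1", i, "A",
                           dna = baseStack(c(A = depth), qual = 40L))
    b <- callPasses(callBayes(so))
    bi <- callPasses(callBinomial(so))
    fr <- callPasses(callFrequency(so))
    b && bi && fr
  }, logical(1))
  expect_gte(mean(agree), 0.99)
})
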