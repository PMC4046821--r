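## Allele frequencies, GRM, PCA, LD and breed-level F-statistics.

test_that("allele frequencies count allele_b over non-missing calls", {
  dos <- rbind(c(1L, 2L, 0L, 0L),
               c(1L, NA, 1L, 1L),
               c(0L, 2L, 2L, 0L))
  g <- toyGenotypes(dos, group = c("g1", "g1", "g2", "g2"))
  af <- alleleFrequencies(g)
  expect_equal(unname(groupFreqs(af)[1, ]), c(0.75, 0))
  ## missing excluded: (1, NA) -> 1 / 2
  expect_equal(unname(groupFreqs(af)[2, "g1"]), 0.5)
  ## mean of group frequencies
  expect_equal(unname(meanFreq(af)[3]), mean(c(0.5, 0.5)))
  ## a group with no calls flags the SNP unusable
  dos2 <- rbind(c(1L, 1L, NA, NA))
  af2 <- alleleFrequencies(toyGenotypes(dos2, group = c("g1", "g1", "g2", "g2")))
  expect_false(af2@usable[1])
})

test_that("GRM matches the hand-computed single-SNP case and basic structure", {
  ## x = (0, 2), p = 0.5: A12 = (0-1)(2-1)/(2*0.5*0.5) = -2
  g <- toyGenotypes(rbind(c(0L, 2L)))
  A <- computeGrm(g)
  expect_equal(A[1, 2], -2)
  expect_equal(A, t(A))
  ## duplicated sample: off-diagonal equals the diagonal entry
  sim <- simulateDataset(simulationConfig(
    chromLengths = c(`1` = 1e6), snpsPerChrom = 400, samplesPerBreed = 4,
    missingRate = 0, seed = 71))
  d <- dosage(sim$genotypes); d[, 2] <- d[, 1]
  A2 <- computeGrm(toyGenotypes(d))
  expect_equal(A2[1, 2], A2[1, 1])
  ## monomorphic-only input errors
  expect_error(computeGrm(toyGenotypes(matrix(2L, 3, 4))), "polymorphic")
})

test_that("GRM of unrelated samples is ~0 off-diagonal and ~1 on the diagonal", {
  sim <- simulateDataset(simulationConfig(
    chromLengths = c(`1` = 5e6), snpsPerChrom = 5000, samplesPerBreed = 5,
    breedsPerGroup = 2, cGroup = 0, cBreed = 0, missingRate = 0.01,
    seed = 73))
  A <- computeGrm(sim$genotypes)
  off <- A[upper.tri(A)]
  ## estimating p from the sample itself centres the row sums of Z, so the
  ## finite-sample expectation of an off-diagonal entry is -1/(n-1)
  expect_lt(abs(mean(off) + 1 / (ncol(A) - 1)),
            3 * sd(off) / sqrt(length(off)))
  expect_lt(abs(mean(diag(A)) - 1), 0.05)
})

test_that("PCA separates simulated subspecies on PC1 and fixes signs", {
  sim <- simulateDataset(simulationConfig(
    chromLengths = c(`1` = 2e6), snpsPerChrom = 1000, samplesPerBreed = 8,
    cGroup = 0.1, seed = 79))
  A <- computeGrm(sim$genotypes)
  pc <- grmPca(A, 2)
  grp <- sampleInfo(sim$genotypes)$group
  s1 <- pc$scores[grp == "taurine", 1]; s2 <- pc$scores[grp == "zebu", 1]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  expect_true(all(diff(pc$values) <= 1e-8))
  ## flipping all dosages leaves |scores| unchanged (label invariance)
  dFlip <- 2L - dosage(sim$genotypes)
  Af <- computeGrm(toyGenotypes(dFlip, group = as.character(grp)))
  pcf <- grmPca(Af, 2)
  expect_equal(abs(unname(pcf$scores)), abs(unname(pc$scores)),
               tolerance = 1e-8)
  ## identity GRM: all eigenvalues equal, no separation axis
  pcI <- grmPca(diag(5), 2)
  expect_true(all(abs(pcI$values - 1) < 1e-12))
})

test_that("r2 matches hand correlations and is relabeling-invariant", {
  g <- toyGenotypes(rbind(c(0L, 0L, 2L, 2L),
                          c(0L, 2L, 0L, 2L),
                          c(0L, 0L, 2L, 2L),
                          c(2L, 2L, 0L, 0L)))
  expect_equal(ldR2(g, 1, 3), 1)
  expect_equal(ldR2(g, 1, 2), 0)
  expect_equal(ldR2(g, 1, 4), 1)      # x -> 2 - x
  expect_warning(r2c <- ldR2(toyGenotypes(rbind(c(1L, 1L, 1L, 1L),
                                                c(0L, 1L, 2L, 1L))), 1, 2),
                 "zero variance")
  expect_true(is.na(r2c))
})

test_that("LD pruning removes the lower-MAF member and audits clean", {
  ## snp1 = (0,1,0,1...) and snp2 = 2*snp1: r2 = 1, MAF 0.25 vs 0.5
  x <- rep(c(0L, 1L), 10)
  dos <- rbind(x, 2L * x, c(rep(0L, 10), rep(1L, 5), rep(2L, 5)))
  g <- toyGenotypes(dos)
  kept <- ldPrune(g, window = 50, step = 10, r2Max = 0.1)
  expect_setequal(kept, c("snp002", "snp003"))
  ## identical vectors tie on MAF -> later position removed
  dos2 <- rbind(x, x, c(rep(0L, 10), rep(1L, 5), rep(2L, 5)))
  kept2 <- ldPrune(toyGenotypes(dos2))
  expect_setequal(kept2, c("snp001", "snp003"))
  ## all pairwise r2 below threshold -> identity
  set.seed(83)
  dInd <- matrix(rbinom(5 * 2000, 2, 0.5), 5, 2000)  # huge n: r2 ~ 1/n
  gInd <- toyGenotypes(dInd)
  expect_identical(ldPrune(gInd), rownames(dosage(gInd)))
  ## post-condition audit on simulated data: no retained pair in any
  ## window exceeds the threshold
  sim <- simulateDataset(simulationConfig(
    chromLengths = c(`1` = 1e6), snpsPerChrom = 120, samplesPerBreed = 10,
    seed = 89))
  keptSim <- ldPrune(sim$genotypes, window = 30, step = 5, r2Max = 0.2)
  idx <- match(keptSim, names(markerMap(sim$genotypes)))
  for (s in seq(1, 120, by = 5)) {
    win <- idx[idx >= s & idx <= s + 29]
    if (length(win) < 2) next
    for (a in seq_along(win)[-length(win)])
      for (b in (a + 1):length(win)) {
        r2 <- suppressWarnings(ldR2(sim$genotypes, win[a], win[b]))
        if (!is.na(r2)) expect_lte(r2, 0.2)
      }
  }
})

test_that("pairwise breed FST is symmetric, ~0 under the null and ~c-bar/2 under drift", {
  sim0 <- simulateDataset(simulationConfig(
    chromLengths = c(`1` = 3e6), snpsPerChrom = 3000, samplesPerBreed = 25,
    cGroup = 0, cBreed = 0, missingRate = 0, seed = 97))
  g0 <- sim0$genotypes
  b <- unique(sampleInfo(g0)$breed)[1:2]
  f0 <- pairwiseFst(g0, b[1], b[2])
  expect_equal(f0, pairwiseFst(g0, b[2], b[1]))
  expect_lt(f0, 0.02)                          # binomial noise bound
  ## two breeds at c_breed = 0.05 each: E[FST] = ((n-1)/n) c = 0.025;
  ## 200 samples/breed keeps binomial inflation (1/(2N)) well below c
  sim <- simulateDataset(simulationConfig(
    chromLengths = c(`1` = 1e7), snpsPerChrom = 10000, breedsPerGroup = 1,
    samplesPerBreed = 200, cGroup = 0, cBreed = 0.05, missingRate = 0,
    seed = 101))
  f <- pairwiseFst(sim$genotypes, "taurine_breed1", "zebu_breed1")
  expect_lt(abs(f - 0.025) / 0.025, 0.10)
})

test_that("FIS matches closed forms and is ~0 under HWE", {
  ## all homozygous at p = 0.5: Hobs 0, Hexp 0.5 -> FIS 1
  hom <- toyGenotypes(matrix(rep(c(0L, 2L), 50), 10, 10, byrow = TRUE),
                      breed = "bx")
  expect_equal(inbreedingFis(hom, "bx"), 1)
  ## all heterozygous at p = 0.5: 1 - 1/0.5 = -1
  het <- toyGenotypes(matrix(1L, 10, 10), breed = "bx")
  expect_equal(inbreedingFis(het, "bx"), -1)
  set.seed(103)
  hw <- toyGenotypes(matrix(rbinom(3000 * 40, 2, 0.5), 3000, 40),
                     breed = "bx")
  expect_lt(abs(inbreedingFis(hw, "bx")), 0.02)
})
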