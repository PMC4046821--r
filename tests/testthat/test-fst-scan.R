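## Per-SNP drift FST, kernel smoothing, region calling, chromosome means.

test_that("snpFst matches analytic values and flags unusable SNPs", {
  af <- freqTable(rbind(c(0.3, 0.3), c(0.0, 1.0), c(0.2, 0.4),
                        c(0.0, 0.0), c(1.0, 1.0)))
  fst <- snpFst(af)
  expect_equal(fst$fst[1], 0)
  expect_equal(fst$fst[2], 1)                       # pbar 0.5, msd 0.25
  expect_equal(fst$fst[3], 0.01 / 0.21)             # 0.0476190...
  expect_false(any(fst$usable[4:5]))                # monomorphic overall
  expect_true(all(is.na(fst$fst[4:5])))             # never 0-filled
})

test_that("snpFst is non-negative, zero iff equal frequencies, label-invariant", {
  set.seed(107)
  for (ngrp in 2:4) {
    p <- matrix(runif(200 * ngrp, 0.02, 0.98), ncol = ngrp)
    f1 <- snpFst(freqTable(p))$fst
    f2 <- snpFst(freqTable(1 - p))$fst             # allele relabeling
    expect_true(all(f1 >= 0))
    expect_equal(f1, f2)
    peq <- matrix(rep(runif(50, 0.1, 0.9), ngrp), ncol = ngrp)
    expect_true(all(snpFst(freqTable(peq))$fst == 0))
  }
})

test_that("smoothing preserves constants and reproduces interior ramps", {
  m <- 60
  cst <- freqTable(matrix(0.3, m, 2))               # fst all 0
  fstC <- snpFst(freqTable(cbind(rep(0.2, m), rep(0.4, m))))
  smC <- smoothTrack(fstC, spanSnps = 15)
  expect_true(all(abs(smC$sfst - fstC$fst[1]) < 1e-12))
  ## linear ramp on equally spaced SNPs: symmetric weights cancel at
  ## interior points
  fstR <- fstC
  mcols(fstR)$fst <- seq(0, 1, length.out = m)
  smR <- smoothTrack(fstR, spanSnps = 15)
  interior <- 8:(m - 7)
  expect_equal(smR$sfst[interior], mcols(fstR)$fst[interior],
               tolerance = 1e-10)
  ## bounded by contributing raw values
  expect_true(all(smR$sfst >= min(mcols(fstR)$fst) - 1e-12 &
                  smR$sfst <= max(mcols(fstR)$fst) + 1e-12))
})

test_that("sliding smoother equals the brute-force k-NN Epanechnikov oracle", {
  set.seed(109)
  for (rep in 1:3) {
    m <- 200
    pos <- sort(sample.int(1e6, m))
    y <- rexp(m, 10)
    af <- freqTable(cbind(rep(0.2, m), rep(0.4, m)), bp = pos)
    fst <- snpFst(af)
    mcols(fst)$fst <- y
    sm <- smoothTrack(fst, spanSnps = 15)
    expect_equal(sm$sfst, naiveSmooth(pos, y, 15), tolerance = 1e-12)
    expect_equal(start(sm), pos)
  }
  ## 15 irregular SNPs, hand-checkable instance
  pos <- c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512, 700, 800, 900, 950, 1000)
  y <- (1:15) / 15
  fst <- snpFst(freqTable(cbind(rep(0.2, 15), rep(0.4, 15)), bp = pos))
  mcols(fst)$fst <- y
  expect_equal(smoothTrack(fst, spanSnps = 5)$sfst, naiveSmooth(pos, y, 5),
               tolerance = 1e-12)
})

test_that("smoothing does not leak across chromosomes and skips tiny ones", {
  m <- 40
  pos <- rep(seq_len(m / 2) * 1000L, 2)
  chrom <- rep(c("1", "2"), each = m / 2)
  af <- freqTable(cbind(rep(0.2, m), rep(0.4, m)), chrom = chrom, bp = pos)
  fst <- snpFst(af)
  mcols(fst)$fst <- c(rep(0, m / 2), rep(1, m / 2))  # step at the boundary
  sm <- smoothTrack(fst, spanSnps = 7)
  expect_true(all(sm$sfst[as.character(seqnames(sm)) == "1"] == 0))
  expect_true(all(sm$sfst[as.character(seqnames(sm)) == "2"] == 1))
  ## single-SNP chromosome skipped with a warning
  af1 <- freqTable(cbind(c(0.2, 0.2, 0.3), c(0.4, 0.4, 0.5)),
                   chrom = c("1", "1", "2"), bp = c(1000L, 2000L, 1000L))
  expect_warning(sm1 <- smoothTrack(snpFst(af1), spanSnps = 3), "skipped")
  expect_true(all(as.character(seqnames(sm1)) == "1"))
})

test_that("block mode yields one unweighted mean per 15-SNP block", {
  m <- 45
  af <- freqTable(cbind(rep(0.2, m), rep(0.4, m)))
  fst <- snpFst(af)
  set.seed(113)
  mcols(fst)$fst <- runif(m)
  sm <- smoothTrack(fst, spanSnps = 15, mode = "block")
  expect_equal(length(sm), 3)
  expect_equal(sm$sfst, c(mean(mcols(fst)$fst[1:15]),
                          mean(mcols(fst)$fst[16:30]),
                          mean(mcols(fst)$fst[31:45])))
  expect_equal(sm$n_snps, rep(15L, 3))
})

test_that("region calling flags planted maxima and merges adjacent points", {
  set.seed(127)
  m <- 300
  v <- runif(m, 0.09, 0.11)
  v[c(50, 51, 200)] <- c(0.5, 0.6, 0.7)      # two adjacent + one isolated
  sm <- GRanges(rep("1", m), IRanges(seq_len(m) * 1000L, width = 1),
                seqinfo = GenomeInfoDb::Seqinfo("1"))
  mcols(sm)$sfst <- v
  reg <- callRegions(sm, topQ = 0.01, bottomQ = 0.01)
  pos <- reg[reg$direction == "positive"]
  expect_equal(length(pos), 2)
  expect_equal(start(pos), c(50000, 200000))
  expect_equal(end(pos), c(51000, 200000))
  expect_equal(pos$n_points, c(2L, 1L))
  expect_equal(pos$extreme_sfst, c(0.6, 0.7))
})

test_that("degenerate all-equal tracks warn and flag ties inclusively", {
  sm <- GRanges(rep("1", 20), IRanges(seq_len(20) * 100L, width = 1))
  mcols(sm)$sfst <- rep(0.2, 20)
  expect_warning(reg <- callRegions(sm), "degenerate")
  expect_true(all(c("positive", "balancing") %in% as.character(reg$direction)))
  expect_equal(max(reg$n_points), 20L)
})

test_that("~1% of points are flagged per side on a continuous track", {
  set.seed(131)
  m <- 10000
  sm <- GRanges(rep("1", m), IRanges(seq_len(m) * 100L, width = 1))
  mcols(sm)$sfst <- rnorm(m)
  reg <- callRegions(sm, topQ = 0.01, bottomQ = 0.01)
  for (dir in c("positive", "balancing")) {
    frac <- sum(reg$n_points[reg$direction == dir]) / m
    expect_lt(abs(frac - 0.01), 0.002)
  }
})

test_that("X-specific thresholds keep a hot X from swamping autosomal calls", {
  set.seed(137)
  m <- 1000
  chrom <- rep(c("1", "2", "X"), c(400, 400, 200))
  v <- c(runif(800, 0, 0.1), runif(200, 0.5, 0.8))   # X far hotter
  sm <- GRanges(chrom, IRanges(unlist(lapply(c(400, 400, 200), seq_len)) * 1000L,
                               width = 1),
                seqinfo = GenomeInfoDb::Seqinfo(c("1", "2", "X")))
  mcols(sm)$sfst <- v
  regPooled <- callRegions(sm, topQ = 0.01, bottomQ = 0.01)
  regSplit <- callRegions(sm, topQ = 0.01, bottomQ = 0.01, xChrom = "X")
  ## pooled thresholds put every positive flag on X; X-specific thresholds
  ## restore autosomal positive calls and call balancing points on X
  expect_true(all(as.character(seqnames(
    regPooled[regPooled$direction == "positive"])) == "X"))
  sp <- regSplit[regSplit$direction == "positive"]
  expect_true(any(as.character(seqnames(sp)) %in% c("1", "2")))
  sb <- regSplit[regSplit$direction == "balancing"]
  expect_true(any(as.character(seqnames(sb)) == "X"))
  expect_error(callRegions(sm, topQ = 0.6, bottomQ = 0.5), "< 1")
})

test_that("chromosome averages: single-SNP chromosome and a hot X", {
  af <- freqTable(cbind(c(0.2, 0.3, 0.1), c(0.4, 0.3, 0.9)),
                  chrom = c("1", "1", "2"), bp = c(1000L, 2000L, 1000L))
  fst <- snpFst(af)
  avg <- chromosomeAverages(fst)
  expect_equal(unname(avg["2"]), fst$fst[3])
  expect_equal(unname(avg["1"]), mean(fst$fst[1:2]))
  ## X simulated at 5x the autosomal drift exceeds autosomal means in
  ## nearly all replicates
  hot <- 0L
  for (s in 1:20) {
    sim <- simulateDataset(simulationConfig(
      chromLengths = c(`1` = 1e6, `2` = 1e6, X = 1e6), snpsPerChrom = 150,
      samplesPerBreed = 10, cMultiplierByChrom = c(X = 5), seed = 200 + s))
    a <- chromosomeAverages(snpFst(alleleFrequencies(sim$genotypes)))
    hot <- hot + (a[["X"]] > max(a[["1"]], a[["2"]]))
  }
  expect_gte(hot, 19)
})

test_that("runScan composes the stages and honours breed-level groupings", {
  sim <- simulateDataset(simulationConfig(
    chromLengths = c(`1` = 2e6, `2` = 2e6), snpsPerChrom = 300,
    samplesPerBreed = 8, seed = 149))
  res <- runScan(sim$genotypes)
  expect_named(res, c("fst", "smoothed", "regions"))
  expect_equal(length(res$fst), 600)
  expect_true(all(res$regions$n_points >= 1))
  ## same code path with breeds of one group as the groups
  g <- sim$genotypes
  sel <- sampleInfo(g)$group == "taurine"
  resW <- runScan(g[, sel], grouping = "breed")
  expect_equal(length(resW$fst), 600)
  expect_error(runScan(g[, sampleInfo(g)$breed == "taurine_breed1"],
                       grouping = "breed"), ">= 2 groups")
})
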