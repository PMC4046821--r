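## Shared fixtures and independent brute-force oracles.  The oracles are
## deliberately naive transcriptions (loops, sort(), all-pairs) so that
## they share no code with the package implementations they check.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(SummarizedExperiment)
})

## small GenotypeData from a dosage matrix (SNPs x samples)
toyGenotypes <- function(dos, chrom = NULL, bp = NULL, breed = NULL,
                         group = NULL) {
  m <- nrow(dos); n <- ncol(dos)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  if (is.null(breed)) breed <- rep("b1", n)
  if (is.null(group)) group <- rep(c("g1", "g2"), length.out = n)
  gr <- GRanges(chrom, IRanges(bp, width = 1),
                seqinfo = GenomeInfoDb::Seqinfo(unique(chrom)))
  names(gr) <- sprintf("snp%03d", seq_len(m))
  gr$allele_a <- "A"; gr$allele_b <- "B"
  storage.mode(dos) <- "integer"
  rownames(dos) <- names(gr)
  GenotypeData(dos, gr, data.frame(
    sample_id = sprintf("s%03d", seq_len(n)), breed = breed, group = group))
}

## AlleleFreqs straight from a frequency matrix (frequency-level input)
freqTable <- function(freq, chrom = NULL, bp = NULL) {
  m <- nrow(freq)
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(bp)) bp <- seq_len(m) * 1000L
  gr <- GRanges(chrom, IRanges(bp, width = 1),
                seqinfo = GenomeInfoDb::Seqinfo(unique(chrom)))
  names(gr) <- sprintf("snp%05d", seq_len(m))
  gr$allele_a <- "A"; gr$allele_b <- "B"
  new("AlleleFreqs", freq = freq, meanFreq = rowMeans(freq),
      usable = rowSums(is.na(freq)) == 0, markers = gr)
}

## brute-force k-NN Epanechnikov smoother on one chromosome
naiveSmooth <- function(x, y, k) {
  n <- length(x)
  k <- min(k, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    b <- sort(abs(x - x[i]))[k]          # k-th smallest distance, self incl.
    keep <- which(abs(x - x[i]) <= b)
    w <- if (b > 0) 0.75 * (1 - (abs(x[keep] - x[i]) / b)^2)
         else rep(1, length(keep))
    out[i] <- sum(w * y[keep]) / sum(w)
  }
  out
}

## brute-force threshold-and-merge region caller
naiveCallRegions <- function(chrom, pos, v, topQ = 0.01, bottomQ = 0.01,
                             xChrom = NULL) {
  res <- data.frame()
  parts <- if (is.null(xChrom)) list(rep(TRUE, length(v)))
           else list(chrom != xChrom, chrom == xChrom)
  flagP <- flagB <- rep(FALSE, length(v))
  for (sel in parts) {
    if (!any(sel)) next
    hi <- as.numeric(quantile(v[sel], 1 - topQ))
    lo <- as.numeric(quantile(v[sel], bottomQ))
    flagP[sel] <- v[sel] >= hi
    flagB[sel] <- v[sel] <= lo
  }
  for (dir in c("positive", "balancing")) {
    flag <- if (dir == "positive") flagP else flagB
    for (ch in unique(chrom)) {
      ii <- which(chrom == ch)
      inRun <- FALSE; runIdx <- integer(0)
      for (j in c(ii, -1)) {          # -1 sentinel flushes the last run
        if (j > 0 && flag[j]) { runIdx <- c(runIdx, j); inRun <- TRUE }
        else if (inRun) {
          res <- rbind(res, data.frame(
            chrom = ch, start = pos[runIdx[1]],
            end = pos[runIdx[length(runIdx)]],
            direction = dir,
            extreme = if (dir == "positive") max(v[runIdx]) else min(v[runIdx]),
            n = length(runIdx)))
          inRun <- FALSE; runIdx <- integer(0)
        }
      }
    }
  }
  res[order(match(res$chrom, unique(chrom)), res$start), , drop = FALSE]
}

## exhaustive greedy LD pruning over ALL pairs (no windows); same
## removal/tie rule: first violating pair in order, drop lower MAF,
## tie -> later position
naivePruneGreedy <- function(dos, r2Max = 0.1) {
  m <- nrow(dos)
  p <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  repeat {
    act <- which(keep)
    if (length(act) < 2) break
    found <- FALSE
    for (ai in seq_len(length(act) - 1)) {
      for (bi in (ai + 1):length(act)) {
        a <- act[ai]; b <- act[bi]
        ok <- !is.na(dos[a, ]) & !is.na(dos[b, ])
        if (sum(ok) < 2 || sd(dos[a, ok]) == 0 || sd(dos[b, ok]) == 0) next
        r2 <- cor(dos[a, ok], dos[b, ok])^2
        if (r2 > r2Max) {
          loser <- if (maf[a] < maf[b]) a else b   # tie -> later position b
          keep[loser] <- FALSE
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    if (!found) break
  }
  which(keep)
}

## naive transcription of the windowed pruning procedure (single chrom)
naivePruneWindowed <- function(dos, window = 50, step = 10, r2Max = 0.1) {
  m <- nrow(dos)
  p <- rowMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep <- rep(TRUE, m)
  startAt <- 1
  repeat {
    endAt <- min(startAt + window - 1, m)
    repeat {
      act <- which(keep)
      act <- act[act >= startAt & act <= endAt]
      removed <- FALSE
      if (length(act) >= 2) {
        for (ai in seq_len(length(act) - 1)) {
          for (bi in (ai + 1):length(act)) {
            a <- act[ai]; b <- act[bi]
            ok <- !is.na(dos[a, ]) & !is.na(dos[b, ])
            if (sum(ok) < 2 || sd(dos[a, ok]) == 0 ||
                sd(dos[b, ok]) == 0) next
            if (cor(dos[a, ok], dos[b, ok])^2 > r2Max) {
              keep[if (maf[a] < maf[b]) a else b] <- FALSE
              removed <- TRUE
              break
            }
          }
          if (removed) break
        }
      }
      if (!removed) break
    }
    if (endAt >= m) break
    startAt <- startAt + step
  }
  which(keep)
}

## all-pairs interval overlap counts (1-based inclusive)
naiveOverlapCounts <- function(rchrom, rstart, rend, achrom, astart, aend) {
  vapply(seq_along(rchrom), function(i) {
    sum(achrom == rchrom[i] & pmax(astart, rstart[i]) <= pmin(aend, rend[i]))
  }, integer(1))
}
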