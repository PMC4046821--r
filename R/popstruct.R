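## Population and LD structure: allele frequencies, GRM, PCA, r2, LD
## pruning, and breed-level F-statistics (pairwise FST, FIS).

#' Per-SNP, per-group allele frequencies
#'
#' Frequency of \code{allele_b}: count of the allele divided by twice the
#' number of non-missing samples, per SNP and group; missing calls are
#' excluded pairwise from the denominators.  The across-group unweighted
#' mean frequency estimates the shared ancestral frequency of the drift
#' model.  SNPs where any group has no non-missing call are flagged
#' unusable and excluded from FST downstream.
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param grouping \code{colData} column name (default \code{"group"}) or a
#'   factor/character vector over samples.
#' @return An \code{\linkS4class{AlleleFreqs}} object.
#' @export
alleleFrequencies <- function(g, grouping = "group") {
  grp <- .resolveGrouping(g, grouping)
  d <- dosage(g)
  lev <- levels(grp)
  freq <- matrix(NA_real_, nrow(d), length(lev),
                 dimnames = list(rownames(d), lev))
  for (lv in lev) {
    sub <- d[, grp == lv, drop = FALSE]
    nOk <- rowSums(!is.na(sub))
    freq[, lv] <- ifelse(nOk > 0, rowSums(sub, na.rm = TRUE) / (2 * nOk), NA)
  }
  usable <- rowSums(is.na(freq)) == 0
  new("AlleleFreqs", freq = freq, meanFreq = rowMeans(freq),
      usable = usable, markers = markerMap(g))
}

#' Genetic relationship matrix
#'
#' VanRaden-style standardized genotype covariance:
#' \deqn{A_{jk} = \frac{1}{m}\sum_i \frac{(x_{ij}-2p_i)(x_{ik}-2p_i)}
#'   {2 p_i (1-p_i)}}
#' over the m usable SNPs, with \code{p_i} the allele_b frequency over all
#' non-missing samples.  Missingness is handled pairwise-complete: each
#' pair's divisor is the number of SNPs where both samples are called.
#' Monomorphic SNPs (MAF 0) are excluded; an input with no polymorphic SNP
#' is an error.  Under Hardy-Weinberg equilibrium the diagonal is ~1 for
#' outbred samples.
#'
#' @param g a \code{\link{GenotypeData}}.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
computeGrm <- function(g) {
  d <- dosage(g)
  nOk <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(nOk, 1))
  keep <- nOk > 0 & p > 0 & p < 1
  if (!any(keep)) stop("no polymorphic SNPs: GRM undefined")
  d <- d[keep, , drop = FALSE]; p <- p[keep]
  Z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  obs <- !is.na(Z)
  Z[!obs] <- 0
  M <- crossprod(obs * 1)          # per-pair count of jointly called SNPs
  A <- crossprod(Z) / pmax(M, 1)
  A[M == 0] <- NA
  dimnames(A) <- list(colData(g)$sample_id, colData(g)$sample_id)
  A
}

#' Principal components of a genetic relationship matrix
#'
#' Top-\code{k} eigenvectors of the GRM, each scaled by the square root of
#' its (non-negative part of the) eigenvalue.  Deterministic up to sign;
#' the sign is fixed so that the largest-magnitude loading of each
#' component is positive.
#'
#' @param grm symmetric matrix from \code{\link{computeGrm}}.
#' @param k number of components (<= number of samples).
#' @return list with \code{scores} (n x k matrix, sample ids as rownames)
#'   and \code{values} (all eigenvalues, non-increasing).
#' @export
grmPca <- function(grm, k = 2) {
  if (any(!is.finite(grm))) stop("GRM contains non-finite entries")
  stopifnot(k >= 1, k <= nrow(grm))
  e <- eigen(grm, symmetric = TRUE)
  vec <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  scores <- sweep(vec, 2, sqrt(pmax(e$values[seq_len(k)], 0)), `*`)
  dimnames(scores) <- list(rownames(grm), paste0("PC", seq_len(k)))
  list(scores = scores, values = e$values)
}

#' Composite LD between two SNPs (squared dosage correlation)
#'
#' Squared Pearson correlation of the two dosage vectors over
#' pairwise-complete samples — the genotype-based (composite) r2 used by
#' PLINK-style pruning; invariant to allele relabeling (x -> 2 - x).
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param snpA,snpB SNP ids or row indices.
#' @return r2 in [0, 1], or \code{NA} (with a warning) when either SNP has
#'   zero variance among the pairwise-complete samples.
#' @export
ldR2 <- function(g, snpA, snpB) {
  d <- dosage(g)
  if (is.character(snpA)) snpA <- match(snpA, rownames(d))
  if (is.character(snpB)) snpB <- match(snpB, rownames(d))
  x <- d[snpA, ]; y <- d[snpB, ]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    warning("r2 undefined: zero variance among pairwise-complete samples")
    return(NA_real_)
  }
  stats::cor(x[ok], y[ok])^2
}

## r2 for all pairs of columns of a dosage submatrix (pairwise-complete)
.r2Matrix <- function(d) {
  ok <- !is.na(d)
  dz <- d; dz[!ok] <- 0
  n <- crossprod(ok * 1)
  S1 <- crossprod(dz, ok * 1)            # sum of x_i over each pair's support
  S2 <- crossprod(dz)                    # sum x*y
  Q <- crossprod(dz^2, ok * 1)           # sum x^2 over pairs
  cov <- S2 / n - (S1 / n) * t(S1 / n)
  vx <- Q / n - (S1 / n)^2
  r2 <- cov^2 / (vx * t(vx))
  r2[!is.finite(r2)] <- NA
  r2
}

#' Prune SNPs by pairwise LD in sliding windows
#'
#' PLINK \code{--indep-pairwise}-style pruning: a window of \code{window}
#' SNPs slides along each chromosome in steps of \code{step} SNPs (windows
#' never span chromosomes).  Within each window, while any pair of
#' still-retained SNPs has r2 strictly greater than \code{r2Max}
#' (pairs visited in map order), the pair member with the lower minor
#' allele frequency is removed (tie: the later map position).  Defaults
#' (50, 10, 0.1) are the standard pruning parameters for structure
#' analyses.
#'
#' @param g a \code{\link{GenotypeData}} with markers sorted by position.
#' @param window window size in SNPs.
#' @param step window shift in SNPs.
#' @param r2Max retention threshold.
#' @return character vector of retained SNP ids, in map order.
#' @export
ldPrune <- function(g, window = 50, step = 10, r2Max = 0.1) {
  stopifnot(window >= 2, step >= 1, r2Max >= 0)
  d <- dosage(g)
  nOk <- rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / (2 * pmax(nOk, 1))
  maf <- pmin(p, 1 - p)
  chroms <- as.character(seqnames(markerMap(g)))
  keep <- rep(TRUE, nrow(d))
  for (ch in unique(chroms)) {
    idx <- which(chroms == ch)
    n <- length(idx)
    startAt <- 1L
    repeat {
      endAt <- min(startAt + window - 1L, n)
      win <- idx[startAt:endAt]
      keep <- .pruneWindow(d, win, keep, maf, r2Max)
      if (endAt >= n) break
      startAt <- startAt + step
    }
  }
  rownames(d)[keep]
}

.pruneWindow <- function(d, win, keep, maf, r2Max) {
  repeat {
    act <- win[keep[win]]
    if (length(act) < 2) return(keep)
    r2 <- .r2Matrix(t(d[act, , drop = FALSE]))
    viol <- which(upper.tri(r2) & !is.na(r2) & r2 > r2Max, arr.ind = TRUE)
    if (!nrow(viol)) return(keep)
    viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
    a <- act[viol[1, 1]]; b <- act[viol[1, 2]]   # a earlier in map order
    loser <- if (maf[a] < maf[b]) a else if (maf[b] < maf[a]) b else b
    keep[loser] <- FALSE
  }
}

#' Genome-wide mean FST between two breeds
#'
#' Applies the drift-model per-SNP estimator (\code{\link{snpFst}}) with
#' the two breeds as the groups and averages over usable SNPs.
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param breedA,breedB breed labels present in \code{colData(g)$breed}.
#' @return single numeric mean FST.
#' @export
pairwiseFst <- function(g, breedA, breedB) {
  sel <- colData(g)$breed %in% c(breedA, breedB)
  if (!any(colData(g)$breed == breedA) || !any(colData(g)$breed == breedB))
    stop("both breeds must have samples")
  sub <- g[, sel]
  fst <- snpFst(alleleFrequencies(sub, grouping = "breed"))
  v <- fst$fst[fst$usable]
  if (!length(v)) stop("no usable SNPs for this breed pair")
  mean(v)
}

#' Wright's FIS (inbreeding coefficient) within a breed
#'
#' \code{FIS = 1 - Hobs / Hexp} with \code{Hobs} the mean (over SNPs) of
#' the observed heterozygote proportion and \code{Hexp} the mean of the
#' Hardy-Weinberg expectation \code{2 p (1 - p)}.
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param breed breed label.
#' @return single numeric FIS.
#' @export
inbreedingFis <- function(g, breed) {
  sel <- colData(g)$breed == breed
  if (!any(sel)) stop("no samples for breed ", breed)
  d <- dosage(g)[, sel, drop = FALSE]
  nOk <- rowSums(!is.na(d))
  use <- nOk > 0
  p <- rowSums(d[use, , drop = FALSE], na.rm = TRUE) / (2 * nOk[use])
  hobs <- mean(rowMeans(d[use, , drop = FALSE] == 1L, na.rm = TRUE))
  hexp <- mean(2 * p * (1 - p))
  if (hexp == 0) stop("expected heterozygosity is zero: FIS undefined")
  1 - hobs / hexp
}
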