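## The analytical core: per-SNP drift-model FST, variable-bandwidth kernel
## smoothing along the genome, percentile thresholding and region
## extraction, per-chromosome summaries, and the composite scan.

#' Per-SNP FST under the pure-drift model
#'
#' For SNP i with group frequencies \eqn{p_{ij}} and across-group mean
#' \eqn{\bar p_i}:
#' \deqn{F_{ST}(i) = \frac{1}{n}\sum_{j=1}^{n}
#'   \frac{(p_{ij}-\bar p_i)^2}{\bar p_i (1-\bar p_i)}}
#' Under pure drift with equal drift parameter c in each of n populations
#' its expectation is \eqn{((n-1)/n)\,c} (frequency level).  The value is
#' invariant to allele relabeling (p -> 1 - p).  SNPs whose mean frequency
#' is 0 or 1 (monomorphic overall), or where any group frequency is
#' undefined, are flagged unusable and carry \code{NA}; they are excluded
#' from smoothing, never zero-filled.
#'
#' @param af an \code{\linkS4class{AlleleFreqs}} from
#'   \code{\link{alleleFrequencies}}.
#' @return GRanges (the marker map) with metadata columns \code{fst} and
#'   \code{usable}.
#' @export
snpFst <- function(af) {
  stopifnot(is(af, "AlleleFreqs"))
  p <- af@freq
  pbar <- af@meanFreq
  usable <- af@usable & !is.na(pbar) & pbar > 0 & pbar < 1
  fst <- rep(NA_real_, nrow(p))
  fst[usable] <- rowMeans((p[usable, , drop = FALSE] - pbar[usable])^2) /
    (pbar[usable] * (1 - pbar[usable]))
  gr <- af@markers
  mcols(gr)$fst <- fst
  mcols(gr)$usable <- usable
  gr
}

## For each index i of sorted positions x, the smallest half-width
## containing the k nearest points (inclusive, self counted) equals the
## width of the best k-window around i.  Two-pointer: the optimal window
## start is non-decreasing in i and the window cost is V-shaped in j.
.knnBandwidth <- function(x, k) {
  n <- length(x)
  k <- min(k, n)
  b <- numeric(n)
  j <- 1L
  cost <- function(j, i) max(x[i] - x[j], x[j + k - 1L] - x[i])
  for (i in seq_len(n)) {
    j <- max(j, i - k + 1L); j <- max(j, 1L)
    while (j + k - 1L < i) j <- j + 1L
    while (j < min(i, n - k + 1L) && cost(j + 1L, i) < cost(j, i))
      j <- j + 1L
    b[i] <- cost(j, i)
  }
  b
}

#' Kernel-smooth a per-SNP FST track along the genome
#'
#' Sliding mode (default): at each usable SNP position x the local
#' bandwidth b(x) is the smallest half-width containing the
#' \code{spanSnps} nearest usable SNPs (inclusive); the smoothed value is
#' the Epanechnikov-kernel (\eqn{K(u) = 0.75(1-u^2)}) weighted mean of the
#' raw values over that support.  The k-nearest-neighbour bandwidth adapts
#' to local marker density, so a fixed SNP count corresponds to a roughly
#' constant physical span on an even map (15 SNPs ~ 50-75 kb at array
#' density).  Block mode: consecutive non-overlapping blocks of
#' \code{spanSnps} usable SNPs each yield one unweighted mean at the
#' block's median position (a trailing shorter block is kept).
#' Chromosomes are processed independently (no cross-chromosome leakage);
#' chromosome edges use the available <= \code{spanSnps} neighbours; a
#' chromosome with fewer than 2 usable SNPs is skipped with a warning.
#'
#' @param fst GRanges from \code{\link{snpFst}} (columns \code{fst},
#'   \code{usable}).
#' @param spanSnps number of SNP values entering each smoothed value.
#' @param mode \code{"sliding"} or \code{"block"}.
#' @return GRanges of evaluation points with metadata columns \code{sfst},
#'   \code{bandwidth} (bp) and \code{n_snps} (contributing SNPs).  Every
#'   smoothed value lies within [min, max] of its contributing raw values.
#' @export
smoothTrack <- function(fst, spanSnps = 15, mode = c("sliding", "block")) {
  mode <- match.arg(mode)
  stopifnot(spanSnps >= 1)
  chroms <- as.character(seqnames(fst))
  outChrom <- character(0); outPos <- integer(0)
  outVal <- outBw <- numeric(0); outN <- integer(0)
  for (ch in unique(chroms)) {
    sel <- which(chroms == ch & mcols(fst)$usable)
    if (length(sel) < 2) {
      warning("chromosome ", ch, " has < 2 usable SNPs; skipped")
      next
    }
    x <- start(fst)[sel]
    y <- mcols(fst)$fst[sel]
    n <- length(x)
    if (mode == "sliding") {
      k <- min(spanSnps, n)
      b <- .knnBandwidth(x, k)
      val <- bw <- numeric(n); cnt <- integer(n)
      for (i in seq_len(n)) {
        lo <- findInterval(x[i] - b[i], x, left.open = TRUE) + 1L
        hi <- findInterval(x[i] + b[i], x)
        d <- x[lo:hi] - x[i]
        w <- if (b[i] > 0) 0.75 * (1 - (d / b[i])^2) else rep(1, hi - lo + 1L)
        val[i] <- sum(w * y[lo:hi]) / sum(w)
        bw[i] <- b[i]; cnt[i] <- hi - lo + 1L
      }
      outChrom <- c(outChrom, rep(ch, n)); outPos <- c(outPos, x)
      outVal <- c(outVal, val); outBw <- c(outBw, bw); outN <- c(outN, cnt)
    } else {
      blk <- ceiling(seq_len(n) / spanSnps)
      for (bi in unique(blk)) {
        ii <- which(blk == bi)
        outChrom <- c(outChrom, ch)
        outPos <- c(outPos, as.integer(floor(stats::median(x[ii]))))
        outVal <- c(outVal, mean(y[ii]))
        outBw <- c(outBw, (max(x[ii]) - min(x[ii])) / 2)
        outN <- c(outN, length(ii))
      }
    }
  }
  gr <- GRanges(outChrom, IRanges(outPos, width = 1),
                seqinfo = GenomeInfoDb::Seqinfo(GenomeInfoDb::seqlevels(fst)))
  mcols(gr)$sfst <- outVal
  mcols(gr)$bandwidth <- outBw
  mcols(gr)$n_snps <- outN
  gr
}

#' Call selection regions from a smoothed FST track
#'
#' Thresholds are the empirical quantiles (linear interpolation of order
#' statistics, \code{quantile} type 7) of the pooled autosomal smoothed
#' values: points with value >= the upper (1 - \code{topQ}) quantile are
#' flagged \code{positive} (candidate positive/directional selection),
#' points <= the lower \code{bottomQ} quantile \code{balancing} (candidate
#' balancing selection / shared purifying pressure).  Ties at a threshold
#' are flagged (inclusive), so a degenerate all-equal track flags
#' everything and raises a warning rather than failing silently.  When
#' \code{xChrom} is given, that chromosome is excluded from the autosomal
#' pool and gets its own pair of quantile thresholds from its own values
#' (the X is typically far more differentiated than the autosomes).
#' Maximal runs of consecutive flagged evaluation points (same chromosome,
#' same direction, no intervening unflagged point) merge into one region.
#'
#' @param sm GRanges from \code{\link{smoothTrack}}.
#' @param topQ,bottomQ tail probabilities (defaults 0.01 each).
#' @param xChrom optional chromosome label to threshold separately.
#' @return GRanges of regions spanning first to last flagged point, with
#'   metadata columns \code{direction} (\code{positive}/\code{balancing}),
#'   \code{extreme_sfst} (max for positive, min for balancing) and
#'   \code{n_points}.
#' @export
callRegions <- function(sm, topQ = 0.01, bottomQ = 0.01, xChrom = NULL) {
  if (!length(sm)) stop("empty smoothed track")
  if (topQ + bottomQ >= 1) stop("topQ + bottomQ must be < 1")
  chroms <- as.character(seqnames(sm))
  v <- mcols(sm)$sfst
  isX <- if (is.null(xChrom)) rep(FALSE, length(sm)) else chroms == xChrom
  flagPos <- flagBal <- rep(FALSE, length(sm))
  for (part in list(which(!isX), which(isX))) {
    if (!length(part)) next
    hi <- stats::quantile(v[part], 1 - topQ, names = FALSE, type = 7)
    lo <- stats::quantile(v[part], bottomQ, names = FALSE, type = 7)
    if (hi <= lo)
      warning("degenerate track: upper threshold <= lower threshold; ",
              "ties flagged in both directions")
    flagPos[part] <- v[part] >= hi
    flagBal[part] <- v[part] <= lo
  }
  .mergeRuns <- function(flag, direction, pick) {
    res <- list()
    for (ch in unique(chroms)) {
      ii <- which(chroms == ch)
      r <- rle(flag[ii])
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (q in which(r$values)) {
        run <- ii[starts[q]:ends[q]]
        res[[length(res) + 1L]] <- data.frame(
          chrom = ch, start = start(sm)[run[1]],
          end = start(sm)[run[length(run)]],
          extreme = pick(v[run]), n = length(run))
      }
    }
    if (!length(res)) return(NULL)
    df <- do.call(rbind, res)
    df$direction <- direction
    df
  }
  df <- rbind(.mergeRuns(flagPos, "positive", max),
              .mergeRuns(flagBal, "balancing", min))
  if (is.null(df))
    return(GRanges(seqinfo = GenomeInfoDb::Seqinfo(GenomeInfoDb::seqlevels(sm))))
  o <- order(match(df$chrom, GenomeInfoDb::seqlevels(sm)), df$start)
  df <- df[o, ]
  gr <- GRanges(df$chrom, IRanges(df$start, df$end),
                seqinfo = GenomeInfoDb::Seqinfo(GenomeInfoDb::seqlevels(sm)))
  mcols(gr)$direction <- factor(df$direction,
                                levels = c("positive", "balancing"))
  mcols(gr)$extreme_sfst <- df$extreme
  mcols(gr)$n_points <- df$n
  gr
}

#' Mean raw FST per chromosome
#'
#' Unweighted mean of the usable per-SNP values, per chromosome.
#'
#' @param fst GRanges from \code{\link{snpFst}}.
#' @return named numeric (chromosomes with >= 1 usable SNP).
#' @export
chromosomeAverages <- function(fst) {
  use <- mcols(fst)$usable
  ch <- as.character(seqnames(fst))[use]
  v <- mcols(fst)$fst[use]
  means <- tapply(v, factor(ch, levels = unique(ch)), mean)
  stats::setNames(as.numeric(means), names(means))
}

#' Run a complete FST selection scan between groups
#'
#' Composition of \code{\link{alleleFrequencies}}, \code{\link{snpFst}},
#' \code{\link{smoothTrack}} and \code{\link{callRegions}}.  The grouping
#' is caller-supplied, so the subspecies contrast and the within-type
#' (breed-level) scans are the same code path.
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param grouping \code{colData} column name or vector; must define >= 2
#'   groups.
#' @param spanSnps,mode passed to \code{\link{smoothTrack}}.
#' @param topQ,bottomQ,xChrom passed to \code{\link{callRegions}}.
#' @return list with \code{fst}, \code{smoothed}, \code{regions}.
#' @export
runScan <- function(g, grouping = "group", spanSnps = 15, topQ = 0.01,
                    bottomQ = 0.01, xChrom = NULL,
                    mode = c("sliding", "block")) {
  grp <- .resolveGrouping(g, grouping)
  if (nlevels(grp) < 2) stop("scan requires >= 2 groups")
  af <- alleleFrequencies(g, grp)
  fst <- snpFst(af)
  sm <- smoothTrack(fst, spanSnps = spanSnps, mode = match.arg(mode))
  regions <- callRegions(sm, topQ = topQ, bottomQ = bottomQ, xChrom = xChrom)
  list(fst = fst, smoothed = sm, regions = regions)
}
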