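## Region annotation: interval overlap (CNV, genes) and hypergeometric
## term over-representation with Bonferroni adjustment.

#' Overlap called regions with an interval annotation set
#'
#' Any-overlap semantics under 1-based inclusive coordinates: interval
#' (a, b) overlaps region (s, e) iff \code{max(a, s) <= min(b, e)}; a
#' single shared base counts.  No minimum overlap fraction is applied.
#'
#' @param regions GRanges of called regions (\code{\link{callRegions}}).
#' @param annot GRanges of annotation intervals (e.g. CNVs or gene spans
#'   from \code{\link{readBedIntervals}}); names are taken from the
#'   \code{name} metadata column, else from \code{names(annot)}.
#' @return \code{regions} with added metadata columns \code{overlaps}
#'   (CharacterList of overlapping interval names) and
#'   \code{overlap_count}.
#' @export
overlapRegions <- function(regions, annot) {
  nm <- if (!is.null(mcols(annot)$name)) mcols(annot)$name
        else if (!is.null(names(annot))) names(annot)
        else as.character(seq_along(annot))
  hits <- findOverlaps(regions, annot, ignore.strand = TRUE)
  lst <- split(nm[S4Vectors::subjectHits(hits)],
               factor(S4Vectors::queryHits(hits),
                      levels = seq_along(regions)))
  mcols(regions)$overlaps <- unname(CharacterList(lst))
  mcols(regions)$overlap_count <- unname(lengths(lst))
  regions
}

#' Hypergeometric term over-representation test
#'
#' For each annotation term, tests whether the query gene set (genes under
#' called regions) contains more genes carrying the term than expected
#' under hypergeometric sampling from the universe: one-sided upper-tail
#' p-value \code{phyper(k - 1, K, N - K, n, lower.tail = FALSE)} with k
#' observed hits, K genes with the term in the universe, n the query set
#' size and N the universe size.  Terms with fewer than \code{minObs}
#' observed hits in the query set are not tested; the Bonferroni factor is
#' the number of terms actually tested.
#'
#' @param regionGenes character vector of query genes (must be a subset of
#'   \code{universe}).
#' @param universe character vector of all candidate genes.
#' @param termMap data.frame with columns \code{gene} and \code{term}
#'   (one row per gene-term assignment).
#' @param minObs minimum observed hits for a term to be tested (default 5).
#' @return data.frame with columns \code{term}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}, \code{p_bonferroni}, sorted by adjusted
#'   p (ties by term).
#' @export
testEnrichment <- function(regionGenes, universe, termMap, minObs = 5) {
  universe <- unique(universe)
  regionGenes <- unique(regionGenes)
  if (!length(universe)) stop("empty gene universe")
  if (!all(regionGenes %in% universe))
    stop("regionGenes must be a subset of the universe")
  if (!all(c("gene", "term") %in% names(termMap)))
    stop("termMap needs columns gene, term")
  tm <- unique(termMap[termMap$gene %in% universe, c("gene", "term")])
  N <- length(universe); n <- length(regionGenes)
  K <- table(tm$term)
  inSet <- tm$gene %in% regionGenes
  k <- table(factor(tm$term[inSet], levels = names(K)))
  tested <- names(K)[k >= minObs]
  if (!length(tested))
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_bonferroni = numeric()))
  kk <- as.integer(k[tested]); KK <- as.integer(K[tested])
  p <- stats::phyper(kk - 1, KK, N - KK, n, lower.tail = FALSE)
  out <- data.frame(term = tested, k = kk, K = KK, n = n, N = N, p = p,
                    p_bonferroni = pmin(1, length(tested) * p))
  out[order(out$p_bonferroni, out$term), , drop = FALSE]
}
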