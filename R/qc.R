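## Sample/SNP quality control: call-rate filters, relatedness filter via
## the GRM off-diagonal, per-group polymorphism status and heterozygosity.

.callRates <- function(g) {
  ok <- !is.na(dosage(g))
  list(sample = stats::setNames(colMeans(ok), colData(g)$sample_id),
       snp = stats::setNames(rowMeans(ok), names(markerMap(g))))
}

#' Filter samples and SNPs by genotype call rate
#'
#' Samples with call rate below \code{sampleMin} are removed first; SNP
#' call rates are then recomputed on the retained samples and SNPs with
#' call rate at or below \code{snpMin} are removed.  The sample threshold
#' is inclusive (retain >= 0.98) and the SNP threshold strict (retain
#' strictly more than 0.95 successful genotypes), mirroring the usual
#' array-QC operators; both are configurable.
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param sampleMin minimum sample call rate (retained if >=), default 0.98.
#' @param snpMin minimum SNP call rate (retained if >), default 0.95.
#' @return list with \code{genotypes} (filtered \code{GenotypeData}) and
#'   \code{report}: per-sample and per-SNP call rates (pre-filter),
#'   \code{droppedSamples} (data.frame sample_id, reason) and
#'   \code{droppedSnps} (character).
#' @export
filterByCallRate <- function(g, sampleMin = 0.98, snpMin = 0.95) {
  stopifnot(sampleMin >= 0, sampleMin <= 1, snpMin >= 0, snpMin <= 1)
  cr <- .callRates(g)
  keepS <- cr$sample >= sampleMin
  if (!any(keepS)) stop("call-rate filter removed all samples")
  g2 <- g[, keepS]
  snpRate <- rowMeans(!is.na(dosage(g2)))
  keepM <- snpRate > snpMin
  g3 <- g2[keepM, ]
  dropped <- names(cr$sample)[!keepS]
  list(genotypes = g3,
       report = list(
         sampleCallRate = cr$sample, snpCallRate = cr$snp,
         droppedSamples = data.frame(
           sample_id = dropped,
           reason = rep("call_rate", length(dropped))),
         droppedSnps = names(markerMap(g2))[!keepM]))
}

#' Remove highly related samples (PI_HAT filter)
#'
#' The genome-wide proportion of alleles shared identical-by-descent
#' between two samples (PI_HAT) is estimated as the off-diagonal entry of
#' the genetic relationship matrix (\code{\link{computeGrm}}) clipped to
#' [0, 1].  While any retained pair exceeds \code{piHatMax} (strict
#' inequality), pairs are visited in sample order and the member with the
#' lower call rate is dropped (tie: the later sample in column order).
#' The GRM is computed once on the input genotypes.
#'
#' @param g a \code{\link{GenotypeData}} with >= 2 samples.
#' @param piHatMax drop threshold, default 0.8 (pairs with PI_HAT strictly
#'   greater are split).
#' @return list with \code{genotypes} and \code{report} (droppedSamples
#'   data.frame with reason \code{"relatedness"}, and the PI_HAT matrix).
#' @export
relatednessFilter <- function(g, piHatMax = 0.8) {
  stopifnot(ncol(g) >= 2, piHatMax >= 0)
  A <- computeGrm(g)
  piHat <- A
  piHat[] <- pmin(1, pmax(0, as.vector(A)))
  diag(piHat) <- NA
  cr <- .callRates(g)$sample
  retained <- colnames(A)
  dropped <- character(0)
  repeat {
    sub <- piHat[retained, retained, drop = FALSE]
    over <- which(upper.tri(sub) & sub > piHatMax, arr.ind = TRUE)
    if (!nrow(over)) break
    over <- over[order(over[, 1], over[, 2]), , drop = FALSE]
    a <- retained[over[1, 1]]; b <- retained[over[1, 2]]
    loser <- if (cr[a] < cr[b]) a else if (cr[b] < cr[a]) b else b
    dropped <- c(dropped, loser)
    retained <- setdiff(retained, loser)
  }
  list(genotypes = g[, match(retained, colData(g)$sample_id)],
       report = list(
         droppedSamples = data.frame(
           sample_id = dropped,
           reason = rep("relatedness", length(dropped))),
         piHat = piHat))
}

#' Classify SNPs by polymorphism status across two groups
#'
#' A SNP is polymorphic within a group iff both alleles are observed among
#' that group's non-missing calls.  Each SNP is classified as
#' \code{"both"}, \code{"<group1>_only"}, \code{"<group2>_only"},
#' \code{"monomorphic"}, or \code{"unclassifiable"} when a group has no
#' non-missing call at the SNP (never silently treated as monomorphic).
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param grouping name of a \code{colData} column (default \code{"group"})
#'   or a factor/character vector over samples; must define exactly 2
#'   groups.
#' @return factor per SNP, named by SNP id.
#' @export
polymorphismStatus <- function(g, grouping = "group") {
  grp <- .resolveGrouping(g, grouping)
  lev <- levels(grp)
  if (length(lev) != 2) stop("polymorphismStatus requires exactly 2 groups")
  d <- dosage(g)
  polyIn <- function(cols) {
    sub <- d[, cols, drop = FALSE]
    nOk <- rowSums(!is.na(sub))
    hasA <- rowSums(sub < 2L, na.rm = TRUE) > 0   # allele_a observed
    hasB <- rowSums(sub > 0L, na.rm = TRUE) > 0   # allele_b observed
    list(poly = hasA & hasB, none = nOk == 0)
  }
  p1 <- polyIn(grp == lev[1]); p2 <- polyIn(grp == lev[2])
  out <- rep("monomorphic", nrow(d))
  out[p1$poly & p2$poly] <- "both"
  out[p1$poly & !p2$poly] <- paste0(lev[1], "_only")
  out[!p1$poly & p2$poly] <- paste0(lev[2], "_only")
  out[p1$none | p2$none] <- "unclassifiable"
  factor(stats::setNames(out, names(markerMap(g))),
         levels = c("both", paste0(lev[1], "_only"), paste0(lev[2], "_only"),
                    "monomorphic", "unclassifiable"))
}

#' Mean observed heterozygosity per group
#'
#' Per SNP and group, the proportion of non-missing genotypes that are
#' heterozygous (dosage 1); averaged over SNPs with at least one
#' non-missing call in the group.
#'
#' @inheritParams polymorphismStatus
#' @return named numeric, one value per group.
#' @export
meanHeterozygosity <- function(g, grouping = "group") {
  grp <- .resolveGrouping(g, grouping)
  d <- dosage(g)
  vapply(levels(grp), function(lv) {
    sub <- d[, grp == lv, drop = FALSE]
    het <- rowMeans(sub == 1L, na.rm = TRUE)  # NaN when all missing
    mean(het[is.finite(het)])
  }, numeric(1))
}

## grouping argument -> factor over samples (column name or vector)
.resolveGrouping <- function(g, grouping) {
  if (is.character(grouping) && length(grouping) == 1) {
    if (!grouping %in% colnames(colData(g)))
      stop("no such sample metadata column: ", grouping)
    grouping <- colData(g)[[grouping]]
  }
  if (length(grouping) != ncol(g))
    stop("grouping must have one value per sample")
  droplevels(as.factor(grouping))
}
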