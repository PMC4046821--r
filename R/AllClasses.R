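#' @import methods
#' @importFrom S4Vectors DataFrame metadata `metadata<-` mcols `mcols<-`
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   countOverlaps
#' @importFrom IRanges IRanges CharacterList
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowRanges
#'   colData
#' @importFrom GenomeInfoDb seqlevels seqlevelsInUse
NULL

#' GenotypeData: diploid SNP genotypes with sample and marker annotation
#'
#' Container for a biallelic SNP dosage matrix (SNPs in rows, samples in
#' columns) together with the marker map (chromosome, base-pair position,
#' alleles) and per-sample metadata (breed, group).  Extends
#' \linkS4class{RangedSummarizedExperiment}: the marker map is the
#' \code{rowRanges}, sample metadata is the \code{colData}, and the single
#' assay \code{"dosage"} holds the count of \code{allele_b} per genotype
#' (0, 1, 2, or \code{NA} for a missing call).
#'
#' Invariants enforced by the validity method: dosages only in
#' \{0, 1, 2, NA\}; unique sample and SNP identifiers; markers sorted by
#' non-decreasing position within each chromosome; missing calls are a
#' distinct \code{NA} sentinel, never conflated with dosage 0.
#'
#' @param dosage integer matrix, SNPs x samples, values 0/1/2/NA (count of
#'   \code{allele_b}).
#' @param markers \link[GenomicRanges]{GRanges} of width-1 marker positions
#'   (1-based), named by SNP id, with metadata columns \code{allele_a} and
#'   \code{allele_b} (single characters; \code{NA} when unobserved).
#' @param samples data.frame or \link[S4Vectors]{DataFrame} with columns
#'   \code{sample_id}, \code{breed}, \code{group}, one row per sample in
#'   column order of \code{dosage}.
#'
#' @return A \code{GenotypeData} object.
#' @examples
#' markers <- GenomicRanges::GRanges("1", IRanges::IRanges(c(100, 200), width = 1))
#' names(markers) <- c("snp1", "snp2")
#' markers$allele_a <- "A"; markers$allele_b <- "B"
#' dos <- matrix(c(0L, 1L, 2L, NA), nrow = 2,
#'               dimnames = list(c("snp1", "snp2"), c("s1", "s2")))
#' g <- GenotypeData(dos, markers,
#'                   data.frame(sample_id = c("s1", "s2"),
#'                              breed = "b1", group = "g1"))
#' g
#' @export
GenotypeData <- function(dosage, markers, samples) {
  samples <- DataFrame(samples)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage))) rownames(dosage) <- names(markers)
  if (is.null(colnames(dosage))) colnames(dosage) <- samples$sample_id
  se <- SummarizedExperiment(assays = list(dosage = dosage),
                             rowRanges = markers, colData = samples)
  new("GenotypeData", se)
}

#' @rdname GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% c(0L, 1L, 2L)))
      msg <- c(msg, "dosage values must be 0, 1, 2 or NA")
  }
  cd <- colData(object)
  need <- c("sample_id", "breed", "group")
  if (!all(need %in% colnames(cd)))
    msg <- c(msg, sprintf("colData must contain %s",
                          paste(need, collapse = ", ")))
  else if (anyDuplicated(cd$sample_id))
    msg <- c(msg, "sample_id must be unique")
  rr <- rowRanges(object)
  if (length(rr)) {
    if (is.null(names(rr)) || anyDuplicated(names(rr)))
      msg <- c(msg, "marker (SNP) ids must be present and unique")
    if (!all(c("allele_a", "allele_b") %in% colnames(mcols(rr))))
      msg <- c(msg, "markers need metadata columns allele_a, allele_b")
    if (any(start(rr) < 1L))
      msg <- c(msg, "marker positions must be >= 1 (1-based)")
    pos <- split(start(rr), as.character(seqnames(rr)))
    if (!all(vapply(pos, function(p) !is.unsorted(p), logical(1))))
      msg <- c(msg, "markers must be sorted by non-decreasing bp within chromosome")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn GenotypeData-class dosage matrix accessor (SNPs x samples)
#' @param x,object a GenotypeData object
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' @rdname GenotypeData-class
#' @export
setMethod("dosage", "GenotypeData", function(x) assay(x, "dosage"))

#' @describeIn GenotypeData-class marker map accessor (GRanges with alleles)
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))

#' @rdname GenotypeData-class
#' @export
setMethod("markerMap", "GenotypeData", function(x) rowRanges(x))

#' @describeIn GenotypeData-class sample metadata accessor (DataFrame)
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname GenotypeData-class
#' @export
setMethod("sampleInfo", "GenotypeData", function(x) colData(x))

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d SNPs x %d samples\n",
              nrow(object), ncol(object)))
  grp <- table(colData(object)$group)
  cat("groups:", paste(sprintf("%s (%d)", names(grp), grp), collapse = ", "),
      "\n")
  cat("chromosomes:", paste(seqlevelsInUse(rowRanges(object)),
                            collapse = ", "), "\n")
  miss <- mean(is.na(assay(object, "dosage")))
  cat(sprintf("missing calls: %.3f%%\n", 100 * miss))
})

#' AlleleFreqs: per-SNP, per-group reference-allele frequencies
#'
#' Holds the frequency of \code{allele_b} for each SNP in each group
#' (\code{freq}, SNPs x groups), the across-group unweighted mean frequency
#' (\code{meanFreq}, the drift model's shared ancestral-frequency estimate),
#' a per-SNP usability flag (every group had at least one non-missing call),
#' and the marker map.  Produced by \code{\link{alleleFrequencies}}; consumed
#' by \code{\link{snpFst}}.
#'
#' @slot freq numeric matrix, SNPs x groups, values in [0, 1] or NA.
#' @slot meanFreq numeric vector, unweighted mean of group frequencies.
#' @slot usable logical vector, frequency defined in every group.
#' @slot markers GRanges marker map aligned with rows of \code{freq}.
#'
#' @exportClass AlleleFreqs
setClass("AlleleFreqs",
         representation(freq = "matrix", meanFreq = "numeric",
                        usable = "logical", markers = "GRanges"))

setValidity("AlleleFreqs", function(object) {
  msg <- character()
  f <- object@freq[!is.na(object@freq)]
  if (length(f) && (min(f) < 0 || max(f) > 1))
    msg <- c(msg, "frequencies must lie in [0, 1]")
  n <- nrow(object@freq)
  if (length(object@meanFreq) != n || length(object@usable) != n ||
      length(object@markers) != n)
    msg <- c(msg, "freq, meanFreq, usable and markers must be aligned")
  if (length(msg)) msg else TRUE
})

#' @describeIn AlleleFreqs-class group frequency matrix accessor
#' @param x,object an AlleleFreqs object
#' @export
setGeneric("groupFreqs", function(x) standardGeneric("groupFreqs"))

#' @rdname AlleleFreqs-class
#' @export
setMethod("groupFreqs", "AlleleFreqs", function(x) x@freq)

#' @describeIn AlleleFreqs-class across-group mean frequency accessor
#' @export
setGeneric("meanFreq", function(x) standardGeneric("meanFreq"))

#' @rdname AlleleFreqs-class
#' @export
setMethod("meanFreq", "AlleleFreqs", function(x) x@meanFreq)

setMethod("show", "AlleleFreqs", function(object) {
  cat(sprintf("AlleleFreqs: %d SNPs x %d groups (%s); %d usable\n",
              nrow(object@freq), ncol(object@freq),
              paste(colnames(object@freq), collapse = ", "),
              sum(object@usable)))
})
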