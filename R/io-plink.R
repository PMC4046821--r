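## PLINK text PED/MAP, BED intervals, and the pipeline's tabular reports.
## Internal coordinates are 1-based inclusive throughout; conversion happens
## only at the BED boundary (BED is 0-based half-open on disk).

#' Read PLINK text PED/MAP genotypes with a sample-to-group table
#'
#' Parses a PLINK text fileset (PED: \code{FID IID PAT MAT SEX PHENO} plus
#' two space-separated allele columns per SNP; MAP: \code{chrom snp_id cM bp})
#' into a \code{\link{GenotypeData}} object.  Group membership (breed and
#' group, e.g. subspecies) comes from a separate tab-separated table with
#' columns \code{sample_id}, \code{breed}, \code{group}; every PED sample
#' (IID) must be present in it.
#'
#' Per SNP, the counted allele \code{allele_b} is the lexicographically
#' larger of the two observed alleles, making the dosage coding
#' deterministic across runs; the drift-model FST estimator is invariant to
#' this labeling (see \code{\link{snpFst}}).  A SNP with a single observed
#' allele gets \code{allele_b = NA} and all dosages 0.  The missing genotype
#' \code{"0 0"} (or any half-missing call) maps to \code{NA}, excluded from
#' all downstream frequency and call-rate denominators.
#'
#' @param pedPath,mapPath paths to the PED and MAP files.
#' @param groupPath path to the sample-to-group TSV (header
#'   \code{sample_id breed group}).
#' @return A \code{\link{GenotypeData}}.
#' @seealso \code{\link{writePedMap}} for the inverse.
#' @export
readPedMap <- function(pedPath, mapPath, groupPath) {
  for (p in c(pedPath, mapPath, groupPath))
    if (!file.exists(p)) stop("input file not found: ", p)
  map <- data.table::fread(mapPath, header = FALSE, sep = "\t",
                           colClasses = list(character = c(1, 2)),
                           data.table = FALSE)
  if (ncol(map) == 1)  # space-separated fallback
    map <- data.table::fread(mapPath, header = FALSE,
                             colClasses = list(character = c(1, 2)),
                             data.table = FALSE)
  if (ncol(map) < 4) stop("MAP file must have 4 columns (chrom id cM bp)")
  names(map)[1:4] <- c("chrom", "snp_id", "cm", "bp")
  if (anyDuplicated(map$snp_id)) stop("duplicate SNP ids in MAP")
  m <- nrow(map)

  ped <- data.table::fread(pedPath, header = FALSE, sep = " ",
                           colClasses = "character", data.table = FALSE)
  if (ncol(ped) != 6 + 2 * m)
    stop(sprintf("PED has %d columns; expected %d for %d MAP markers",
                 ncol(ped), 6 + 2 * m, m))
  ids <- ped[[2]]
  if (anyDuplicated(ids)) stop("duplicate sample ids (IID) in PED")

  groups <- utils::read.table(groupPath, header = TRUE, sep = "\t",
                              colClasses = "character")
  if (!all(c("sample_id", "breed", "group") %in% names(groups)))
    stop("group table needs columns sample_id, breed, group")
  missing_ids <- setdiff(ids, groups$sample_id)
  if (length(missing_ids))
    stop("PED samples absent from group table: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  groups <- groups[match(ids, groups$sample_id), , drop = FALSE]

  a1 <- as.matrix(ped[, 6 + 2 * seq_len(m) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(m), drop = FALSE])
  a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA; a2[half] <- NA

  dos <- matrix(NA_integer_, nrow = m, ncol = length(ids))
  allele_a <- allele_b <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    obs <- sort(unique(c(a1[, i], a2[, i])))
    obs <- obs[!is.na(obs)]
    if (length(obs) > 2)
      stop(sprintf("SNP %s has >2 alleles: %s", map$snp_id[i],
                   paste(obs, collapse = "/")))
    if (length(obs) >= 1) allele_a[i] <- obs[1]
    if (length(obs) == 2) allele_b[i] <- obs[2]
    if (!is.na(allele_b[i]))
      dos[i, ] <- (a1[, i] == allele_b[i]) + (a2[, i] == allele_b[i])
    else
      dos[i, ][!is.na(a1[, i])] <- 0L
  }
  markers <- GRanges(map$chrom, IRanges(as.integer(map$bp), width = 1),
                     seqinfo = GenomeInfoDb::Seqinfo(unique(map$chrom)))
  names(markers) <- map$snp_id
  mcols(markers)$allele_a <- allele_a
  mcols(markers)$allele_b <- allele_b
  GenotypeData(dos, markers,
               data.frame(sample_id = ids, breed = groups$breed,
                          group = groups$group))
}

#' Write a GenotypeData object as PLINK text PED/MAP (and group table)
#'
#' Dosage 0 is written as two copies of \code{allele_a}, 1 as
#' \code{allele_a allele_b}, 2 as two copies of \code{allele_b}, and missing
#' as \code{"0 0"}.  PED leading columns are \code{FID = breed},
#' \code{IID = sample_id}, \code{PAT = MAT = 0}, \code{SEX = 0},
#' \code{PHENO = -9}.  Output is byte-deterministic for a given object.
#'
#' @param g a \code{\link{GenotypeData}}.
#' @param pedPath,mapPath output paths.
#' @param groupPath optional path for the sample-to-group TSV; written when
#'   non-NULL so that \code{\link{readPedMap}} can restore sample metadata.
#' @return Invisibly, the PED path.
#' @export
writePedMap <- function(g, pedPath, mapPath, groupPath = NULL) {
  rr <- markerMap(g)
  map <- data.frame(chrom = as.character(seqnames(rr)), snp_id = names(rr),
                    cm = 0, bp = start(rr))
  utils::write.table(map, mapPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  d <- dosage(g)
  aa <- mcols(rr)$allele_a
  ab <- mcols(rr)$allele_b
  if (any(d[!is.na(d)] > 0L & is.na(ab[row(d)][!is.na(d)])))
    stop("cannot encode dosage > 0 at a SNP with undefined allele_b")
  aa[is.na(aa)] <- "0"
  first  <- matrix(aa[row(d)], nrow = nrow(d))  # dosage 0/1 -> allele_a
  second <- matrix(aa[row(d)], nrow = nrow(d))
  i2 <- which(d == 2L); i1 <- which(d >= 1L); imiss <- which(is.na(d))
  first[i2] <- ab[row(d)[i2]]
  second[i1] <- ab[row(d)[i1]]
  first[imiss] <- "0"; second[imiss] <- "0"
  geno <- matrix(paste(first, second), nrow = nrow(d))
  cd <- colData(g)
  lines <- vapply(seq_len(ncol(d)), function(j) {
    paste(c(cd$breed[j], cd$sample_id[j], "0", "0", "0", "-9", geno[, j]),
          collapse = " ")
  }, character(1))
  writeLines(lines, pedPath)
  if (!is.null(groupPath))
    utils::write.table(as.data.frame(cd[, c("sample_id", "breed", "group")]),
                       groupPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pedPath)
}

#' Read a BED interval file into 1-based inclusive GRanges
#'
#' BED coordinates are 0-based half-open on disk; internally the package
#' uses 1-based inclusive coordinates throughout, so a BED line
#' \code{chr1 100 200 cnv1} becomes the range \code{chr1:101-200}.
#' Overlapping records are preserved unmerged.  An empty file yields an
#' empty GRanges.
#'
#' @param path path to a BED3/BED4 (or richer) file.
#' @return \link[GenomicRanges]{GRanges}; BED \code{name} (when present) is
#'   kept in the \code{name} metadata column.
#' @export
readBedIntervals <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (file.size(path) == 0 ||
      !length(readLines(path, n = 1L, warn = FALSE)))
    return(GRanges())
  gr <- rtracklayer::import(path, format = "BED")
  if (any(width(gr) < 1))
    stop("BED record with start >= end")
  gr
}

#' Write called selection regions as a TSV report
#'
#' One row per region with columns \code{region_id}, \code{chrom},
#' \code{start_bp}, \code{end_bp}, \code{extreme_smoothed_fst},
#' \code{direction}, \code{n_points}, \code{overlapping_cnv_count}.  Rows
#' are sorted by (chromosome, start); region ids are \code{P1, P2, ...} for
#' positive and \code{B1, B2, ...} for balancing regions in that sort order.
#' An empty region set writes a header-only file.
#'
#' @param regions GRanges as returned by \code{\link{callRegions}} (metadata
#'   columns \code{direction}, \code{extreme_sfst}, \code{n_points}).
#' @param path output path.
#' @param cnv optional GRanges of CNV intervals (1-based inclusive, e.g.
#'   from \code{\link{readBedIntervals}}); when supplied,
#'   \code{overlapping_cnv_count} is the number of CNV records overlapping
#'   each region, otherwise \code{NA}.
#' @return Invisibly, the report as a data.frame.
#' @export
writeRegionReport <- function(regions, path, cnv = NULL) {
  if (length(regions)) {
    o <- order(match(as.character(seqnames(regions)), seqlevels(regions)),
               start(regions))
    regions <- regions[o]
    ncnv <- if (is.null(cnv)) NA_integer_ else
      countOverlaps(regions, cnv, ignore.strand = TRUE)
    dir <- as.character(regions$direction)
    id <- character(length(regions))
    id[dir == "positive"] <- paste0("P", seq_len(sum(dir == "positive")))
    id[dir == "balancing"] <- paste0("B", seq_len(sum(dir == "balancing")))
    df <- data.frame(region_id = id,
                     chrom = as.character(seqnames(regions)),
                     start_bp = start(regions), end_bp = end(regions),
                     extreme_smoothed_fst = regions$extreme_sfst,
                     direction = dir, n_points = regions$n_points,
                     overlapping_cnv_count = ncnv)
  } else {
    df <- data.frame(region_id = character(), chrom = character(),
                     start_bp = integer(), end_bp = integer(),
                     extreme_smoothed_fst = numeric(),
                     direction = character(), n_points = integer(),
                     overlapping_cnv_count = integer())
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Write a raw or smoothed FST track as TSV
#'
#' @param track GRanges with a value metadata column (\code{fst} or
#'   \code{sfst}).
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeTrack <- function(track, path) {
  valcol <- intersect(c("sfst", "fst"), colnames(mcols(track)))[1]
  df <- data.frame(chrom = as.character(seqnames(track)), bp = start(track),
                   value = mcols(track)[[valcol]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
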