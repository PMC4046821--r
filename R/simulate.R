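## Hierarchical pure-drift genotype simulator.  Two levels of drift
## (ancestor -> group/subspecies -> breed) plus binomial genotype sampling
## reproduce the moment structure the FST estimator assumes, and injected
## intervals of elevated or suppressed group-level drift provide ground
## truth for region-recovery tests.

#' Simulation configuration for the drift-model genotype generator
#'
#' Builds and validates the parameter set consumed by
#' \code{\link{simulateDataset}}.  Defaults emulate a dense-array scan of
#' two diverged subspecies: 5 chromosomes of 10 Mb carrying 2,000 evenly
#' spaced SNPs each (5 kb gaps, the density regime of a high-density bovine
#' array), 2 groups x 3 breeds x 25 samples, group-level drift
#' \code{cGroup = 0.1} (the magnitude of taurine-zebu differentiation),
#' breed-level drift \code{cBreed = 0.05}, ancestral frequencies uniform on
#' (0.05, 0.95) (array ascertainment against rare variants), and 0.2%
#' missing calls.
#'
#' @param chromLengths named numeric, chromosome lengths in bp.
#' @param snpsPerChrom integer, SNPs per chromosome.
#' @param groupNames character, group (subspecies) labels.
#' @param breedsPerGroup,samplesPerBreed integers.
#' @param cGroup drift parameter ancestor -> group; scalar or one value per
#'   group.  Dimensionless, >= 0; a descendant frequency has variance
#'   \code{c * pi * (1 - pi)} around the ancestral frequency \code{pi}.
#' @param cBreed drift parameter group -> breed (scalar).
#' @param cMultiplierByChrom optional named numeric scaling \code{cGroup}
#'   on specific chromosomes (e.g. a 5x-drifted X).
#' @param ancestralFreqRange length-2 numeric in (0, 1).
#' @param selectedIntervals data.frame with columns \code{chrom},
#'   \code{start}, \code{end} (bp, 1-based inclusive), \code{direction}
#'   (\code{"positive"} or \code{"balancing"}) and \code{multiplier}.
#'   Within a positive interval group-level drift is \code{cGroup *
#'   multiplier} (multiplier > 1); within a balancing interval group
#'   frequencies are pulled back to the shared ancestral frequency, the
#'   multiplier (< 1) scaling any residual jitter (0 = exact equality).
#' @param missingRate probability a genotype call is masked missing.
#' @param positionJitter fraction of the inter-SNP spacing by which marker
#'   positions are uniformly jittered (0 = evenly spaced), to exercise the
#'   variable-bandwidth smoother on irregular maps.
#' @param seed integer; fully determines the output.
#' @return A validated list of class \code{SimulationConfig}.
#' @export
simulationConfig <- function(chromLengths = stats::setNames(rep(1e7, 5),
                                                            as.character(1:5)),
                             snpsPerChrom = 2000L,
                             groupNames = c("taurine", "zebu"),
                             breedsPerGroup = 3L,
                             samplesPerBreed = 25L,
                             cGroup = 0.1,
                             cBreed = 0.05,
                             cMultiplierByChrom = NULL,
                             ancestralFreqRange = c(0.05, 0.95),
                             selectedIntervals = NULL,
                             missingRate = 0.002,
                             positionJitter = 0,
                             seed = 1L) {
  stopifnot(length(chromLengths) >= 1, !is.null(names(chromLengths)),
            snpsPerChrom >= 1, length(groupNames) >= 2,
            breedsPerGroup >= 1, samplesPerBreed >= 1,
            all(cGroup >= 0), cBreed >= 0,
            missingRate >= 0, missingRate <= 1,
            positionJitter >= 0, positionJitter <= 1)
  if (!(length(cGroup) %in% c(1L, length(groupNames))))
    stop("cGroup must be scalar or one value per group")
  r <- ancestralFreqRange
  if (length(r) != 2 || r[1] <= 0 || r[2] >= 1 || r[1] > r[2])
    stop("ancestralFreqRange must satisfy 0 < lo <= hi < 1")
  if (!is.null(selectedIntervals) && nrow(selectedIntervals)) {
    si <- selectedIntervals
    need <- c("chrom", "start", "end", "direction", "multiplier")
    if (!all(need %in% names(si)))
      stop("selectedIntervals needs columns ", paste(need, collapse = ", "))
    if (!all(si$direction %in% c("positive", "balancing")))
      stop("selectedIntervals direction must be positive or balancing")
    if (!all(si$chrom %in% names(chromLengths)))
      stop("selected interval on unknown chromosome")
    if (any(si$start < 1 | si$end > chromLengths[si$chrom] |
            si$start > si$end))
      stop("selected interval outside chromosome bounds")
    if (any(si$direction == "positive" & si$multiplier <= 1))
      stop("positive intervals need multiplier > 1")
    if (any(si$direction == "balancing" & si$multiplier >= 1))
      stop("balancing intervals need multiplier < 1")
    if (any(si$multiplier < 0)) stop("multiplier must be >= 0")
  }
  structure(list(chromLengths = chromLengths,
                 snpsPerChrom = as.integer(snpsPerChrom),
                 groupNames = groupNames,
                 breedsPerGroup = as.integer(breedsPerGroup),
                 samplesPerBreed = as.integer(samplesPerBreed),
                 cGroup = rep_len(cGroup, length(groupNames)),
                 cBreed = cBreed,
                 cMultiplierByChrom = cMultiplierByChrom,
                 ancestralFreqRange = r,
                 selectedIntervals = selectedIntervals,
                 missingRate = missingRate,
                 positionJitter = positionJitter,
                 seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Draw ancestral allele frequencies
#'
#' The shared origin population's frequency \code{pi} per SNP, i.i.d.
#' uniform on \code{(lo, hi)}.  Uses R's global RNG; seed with
#' \code{set.seed} for reproducibility.
#'
#' @param n number of SNPs.
#' @param range length-2 numeric, \code{0 < lo <= hi < 1}.
#' @return numeric vector of length \code{n}.
#' @export
drawAncestralFreqs <- function(n, range = c(0.05, 0.95)) {
  if (length(range) != 2 || range[1] <= 0 || range[2] >= 1 ||
      range[1] > range[2])
    stop("range must satisfy 0 < lo <= hi < 1")
  stats::runif(n, range[1], range[2])
}

#' Drift descendant allele frequencies from an ancestral vector
#'
#' Pure-drift transition: each descendant frequency is drawn
#' \code{Normal(pi, c * pi * (1 - pi))} and clamped to [0, 1]; the boundary
#' mass created by clamping stands in for fixation/loss of the allele.
#' \code{c = 0} returns \code{pi} unchanged.
#'
#' @param pi numeric vector of ancestral frequencies in [0, 1].
#' @param c drift parameter, scalar or per-SNP vector, >= 0.
#' @return numeric vector of descendant frequencies in [0, 1].
#' @export
driftFrequencies <- function(pi, c = 0.1) {
  if (any(c < 0)) stop("drift parameter c must be >= 0")
  if (any(pi < 0 | pi > 1)) stop("ancestral frequencies must lie in [0, 1]")
  pmin(1, pmax(0, stats::rnorm(length(pi), pi, sqrt(c * pi * (1 - pi)))))
}

#' Simulate a hierarchical drift genotype dataset with ground truth
#'
#' Draws ancestral frequencies once, drifts them to group (subspecies)
#' level with \code{cGroup} (modified inside any configured selected
#' intervals), drifts each group frequency to breed level with
#' \code{cBreed}, samples diploid genotypes Binomial(2, breed frequency)
#' per sample, and masks calls missing at \code{missingRate}.  Marker
#' positions are evenly spaced along each chromosome (optionally jittered).
#' The seed in the config fully determines the output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return list with elements \code{genotypes} (a
#'   \code{\link{GenotypeData}}) and \code{truth} (class
#'   \code{SimulationTruth}: realized group and breed frequencies,
#'   ancestral frequencies, the configured selected intervals as a GRanges,
#'   and the drift parameters).
#' @export
simulateDataset <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  chroms <- names(config$chromLengths)
  nper <- config$snpsPerChrom
  m <- nper * length(chroms)

  pos <- integer(0); chromv <- character(0)
  for (ch in chroms) {
    L <- config$chromLengths[[ch]]
    spacing <- L / nper
    p <- (seq_len(nper) - 0.5) * spacing
    if (config$positionJitter > 0)
      p <- p + stats::runif(nper, -1, 1) * config$positionJitter * spacing
    p <- pmin(L, pmax(1, round(p)))
    p <- sort(as.integer(p))
    # enforce strictly increasing positions after rounding/jitter
    for (i in seq_len(nper - 1) + 1L)
      if (p[i] <= p[i - 1]) p[i] <- p[i - 1] + 1L
    pos <- c(pos, as.integer(p)); chromv <- c(chromv, rep(ch, nper))
  }

  pi <- drawAncestralFreqs(m, config$ancestralFreqRange)

  ## per-SNP effective group drift: chromosome multiplier, then intervals
  cmul <- rep(1, m)
  if (!is.null(config$cMultiplierByChrom)) {
    hit <- chromv %in% names(config$cMultiplierByChrom)
    cmul[hit] <- config$cMultiplierByChrom[chromv[hit]]
  }
  balancing <- rep(FALSE, m)
  balMul <- rep(1, m)
  si <- config$selectedIntervals
  if (!is.null(si) && nrow(si)) {
    for (r in seq_len(nrow(si))) {
      inside <- chromv == si$chrom[r] & pos >= si$start[r] & pos <= si$end[r]
      if (si$direction[r] == "positive") {
        cmul[inside] <- cmul[inside] * si$multiplier[r]
      } else {
        balancing[inside] <- TRUE
        balMul[inside] <- si$multiplier[r]
      }
    }
  }

  ngrp <- length(config$groupNames)
  groupFreq <- matrix(NA_real_, m, ngrp,
                      dimnames = list(NULL, config$groupNames))
  for (j in seq_len(ngrp)) {
    cvec <- config$cGroup[j] * cmul
    cvec[balancing] <- config$cGroup[j] * balMul[balancing]
    groupFreq[, j] <- driftFrequencies(pi, cvec)
  }

  nb <- config$breedsPerGroup
  ns <- config$samplesPerBreed
  breedNames <- as.vector(outer(seq_len(nb), config$groupNames,
                                function(k, g) paste0(g, "_breed", k)))
  breedFreq <- matrix(NA_real_, m, ngrp * nb,
                      dimnames = list(NULL, breedNames))
  dos <- matrix(NA_integer_, m, ngrp * nb * ns)
  sample_id <- character(ngrp * nb * ns)
  breed <- group <- character(ngrp * nb * ns)
  col <- 0L
  for (j in seq_len(ngrp)) for (k in seq_len(nb)) {
    bf <- driftFrequencies(groupFreq[, j], config$cBreed)
    bname <- paste0(config$groupNames[j], "_breed", k)
    breedFreq[, bname] <- bf
    idx <- col + seq_len(ns)
    dos[, idx] <- stats::rbinom(m * ns, 2L, rep(bf, times = ns))
    sample_id[idx] <- sprintf("%s_s%02d", bname, seq_len(ns))
    breed[idx] <- bname
    group[idx] <- config$groupNames[j]
    col <- col + ns
  }
  if (config$missingRate > 0)
    dos[stats::runif(length(dos)) < config$missingRate] <- NA_integer_

  snp_id <- sprintf("snp_%s_%05d", chromv,
                    rep(seq_len(nper), times = length(chroms)))
  markers <- GRanges(chromv, IRanges(pos, width = 1),
                     seqinfo = GenomeInfoDb::Seqinfo(chroms))
  names(markers) <- snp_id
  mcols(markers)$allele_a <- "A"
  mcols(markers)$allele_b <- "B"
  rownames(dos) <- snp_id
  g <- GenotypeData(dos, markers,
                    data.frame(sample_id = sample_id, breed = breed,
                               group = group))
  truthIntervals <- if (!is.null(si) && nrow(si))
    GRanges(si$chrom, IRanges(si$start, si$end),
            direction = si$direction, multiplier = si$multiplier,
            seqinfo = GenomeInfoDb::Seqinfo(chroms))
  else GRanges(seqinfo = GenomeInfoDb::Seqinfo(chroms))
  truth <- structure(list(ancestralFreq = pi, groupFreq = groupFreq,
                          breedFreq = breedFreq,
                          selectedIntervals = truthIntervals,
                          cGroup = stats::setNames(config$cGroup,
                                                   config$groupNames),
                          cBreed = config$cBreed),
                     class = "SimulationTruth")
  list(genotypes = g, truth = truth)
}

#' Write simulator outputs (PED/MAP, group table, truth TSV, intervals BED)
#'
#' @param sim result of \code{\link{simulateDataset}}.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @return Invisibly, named vector of the written paths.
#' @export
writeSimulation <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(ped = file.path(dir, paste0(prefix, ".ped")),
             map = file.path(dir, paste0(prefix, ".map")),
             groups = file.path(dir, paste0(prefix, ".groups.tsv")),
             truth = file.path(dir, paste0(prefix, ".truth.tsv")),
             bed = file.path(dir, paste0(prefix, ".intervals.bed")))
  writePedMap(sim$genotypes, paths["ped"], paths["map"], paths["groups"])
  tr <- sim$truth
  rr <- markerMap(sim$genotypes)
  df <- data.frame(snp_id = names(rr), chrom = as.character(seqnames(rr)),
                   bp = start(rr), ancestral_freq = tr$ancestralFreq,
                   as.data.frame(tr$groupFreq))
  utils::write.table(df, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  iv <- tr$selectedIntervals
  bed <- data.frame(chrom = as.character(seqnames(iv)), start = start(iv) - 1L,
                    end = end(iv),
                    name = if (length(iv)) iv$direction else character(0))
  utils::write.table(bed, paths["bed"], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
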