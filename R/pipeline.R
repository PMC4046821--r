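## End-to-end orchestration: a YAML run configuration whose defaults are
## the scan's standard parameterization, and a driver that chains
## simulate-or-read -> QC -> LD pruning (structure only) -> GRM/PCA ->
## FST scans (group contrast + within-group breed scans) -> annotation.
## The pruned SNP set feeds only the population-structure steps; the scan
## always uses the full QC-passed marker set.

.defaultParams <- function() {
  list(sample_call_rate = 0.98, snp_call_rate = 0.95, pi_hat_max = 0.8,
       prune_window = 50, prune_step = 10, prune_r2 = 0.1,
       span_snps = 15, top_q = 0.01, bottom_q = 0.01, x_chrom = NULL,
       smooth_mode = "sliding", min_obs = 5, pca_k = 2)
}

#' Read a pipeline run configuration (YAML)
#'
#' Missing parameters fall back to the scan's standard settings: call-rate
#' thresholds 0.98 (sample) / 0.95 (SNP), PI_HAT 0.8, pruning 50/10/0.1,
#' smoothing span 15 SNPs, top/bottom 1\% thresholds, enrichment minimum
#' 5 observed hits.  Recognised top-level keys: \code{ped}, \code{map},
#' \code{groups} (input paths) or \code{simulation} (a block of
#' \code{\link{simulationConfig}} arguments), \code{cnv_bed},
#' \code{gene_bed}, \code{term_map}, \code{seed}, \code{outdir}, plus any
#' parameter name above.
#'
#' @param path YAML file path.
#' @return list of class \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  params <- .defaultParams()
  for (nm in names(params))
    if (!is.null(cfg[[nm]])) params[[nm]] <- cfg[[nm]]
  cfg$params <- params
  if (is.null(cfg$seed)) cfg$seed <- 1L
  structure(cfg, class = "RunConfig")
}

#' Run the full selection-scan pipeline
#'
#' Stages: (1) simulate genotypes (when the config has a
#' \code{simulation} block) or read PED/MAP + group table; (2) call-rate
#' and relatedness QC; (3) LD pruning, used for the population-structure
#' stage only; (4) GRM and PCA on the pruned markers; (5) FST scans on the
#' full (unpruned) QC-passed markers: the group contrast plus a
#' within-group breed-level scan for every group with >= 2 breeds;
#' (6) optional annotation (CNV overlap counts in the region reports,
#' gene-interval overlap and term enrichment for balancing and positive
#' regions).  Every run writes a provenance JSON (config, seed, package
#' and R versions); all randomness flows from the single seed, and a given
#' config + seed reproduces every output byte-identically.
#'
#' @param config a \code{RunConfig} from \code{\link{readRunConfig}}, or a
#'   path to a YAML config.
#' @param outdir output directory (overrides the config's).
#' @param seed integer seed (overrides the config's).
#' @return Invisibly, a list with the main in-memory results (genotypes,
#'   qc, grm, pca, scans) and \code{paths} of the written files.
#' @export
runPipeline <- function(config, outdir = NULL, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  stopifnot(inherits(config, "RunConfig") || is.list(config))
  if (is.null(config$params)) config$params <- .defaultParams()
  prm <- config$params
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(outdir)) config$outdir <- outdir
  if (is.null(config$outdir)) stop("no output directory given")

  ## validate inputs before writing anything (no partial outputs)
  simulated <- !is.null(config$simulation)
  if (!simulated) {
    for (key in c("ped", "map", "groups")) {
      if (is.null(config[[key]])) stop("config lacks input path: ", key)
      if (!file.exists(config[[key]]))
        stop("input file not found: ", config[[key]])
    }
  }
  for (key in c("cnv_bed", "gene_bed", "term_map"))
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      stop("input file not found: ", config[[key]])

  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$outdir, ...)
  paths <- character(0)

  if (simulated) {
    simArgs <- config$simulation
    simArgs$seed <- config$seed
    if (!is.null(simArgs$selectedIntervals))
      simArgs$selectedIntervals <- as.data.frame(simArgs$selectedIntervals)
    if (!is.null(simArgs$chromLengths))
      simArgs$chromLengths <- unlist(simArgs$chromLengths)
    sim <- do.call(simulationConfig, simArgs)
    sim <- simulateDataset(sim)
    paths <- c(paths, writeSimulation(sim, config$outdir, "sim"))
    g <- sim$genotypes
    truth <- sim$truth
  } else {
    g <- readPedMap(config$ped, config$map, config$groups)
    truth <- NULL
  }

  qc1 <- filterByCallRate(g, prm$sample_call_rate, prm$snp_call_rate)
  qc2 <- relatednessFilter(qc1$genotypes, prm$pi_hat_max)
  g <- qc2$genotypes
  qcTab <- rbind(qc1$report$droppedSamples, qc2$report$droppedSamples)
  utils::write.table(qcTab, out("qc_dropped_samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(qc1$report$droppedSnps, out("qc_dropped_snps.txt"))
  paths <- c(paths, out("qc_dropped_samples.tsv"), out("qc_dropped_snps.txt"))

  kept <- ldPrune(g, prm$prune_window, prm$prune_step, prm$prune_r2)
  writeLines(kept, out("pruned_snps.txt"))
  gPruned <- g[match(kept, names(markerMap(g))), ]
  A <- computeGrm(gPruned)
  utils::write.table(round(A, 6), out("grm.tsv"), sep = "\t", quote = FALSE)
  pca <- grmPca(A, k = min(prm$pca_k, nrow(A)))
  utils::write.table(data.frame(sample_id = rownames(pca$scores),
                                round(pca$scores, 6)),
                     out("pca.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, out("pruned_snps.txt"), out("grm.tsv"), out("pca.tsv"))

  cnv <- if (!is.null(config$cnv_bed)) readBedIntervals(config$cnv_bed)
  scans <- list()
  scanSpecs <- list(list(name = "group", g = g, grouping = "group"))
  for (gv in unique(colData(g)$group)) {
    sel <- colData(g)$group == gv
    if (length(unique(colData(g)$breed[sel])) >= 2)
      scanSpecs[[length(scanSpecs) + 1L]] <-
        list(name = paste0("within_", gv), g = g[, sel], grouping = "breed")
  }
  for (sp in scanSpecs) {
    res <- runScan(sp$g, grouping = sp$grouping, spanSnps = prm$span_snps,
                   topQ = prm$top_q, bottomQ = prm$bottom_q,
                   xChrom = prm$x_chrom, mode = prm$smooth_mode)
    writeTrack(res$fst, out(sprintf("fst_%s.tsv", sp$name)))
    writeTrack(res$smoothed, out(sprintf("sfst_%s.tsv", sp$name)))
    writeRegionReport(res$regions, out(sprintf("regions_%s.tsv", sp$name)),
                      cnv = cnv)
    utils::write.table(
      data.frame(chrom = names(chromosomeAverages(res$fst)),
                 mean_fst = chromosomeAverages(res$fst)),
      out(sprintf("chrom_fst_%s.tsv", sp$name)), sep = "\t",
      quote = FALSE, row.names = FALSE)
    paths <- c(paths, out(sprintf("regions_%s.tsv", sp$name)))
    scans[[sp$name]] <- res
  }

  if (!is.null(config$gene_bed) && !is.null(config$term_map)) {
    genes <- readBedIntervals(config$gene_bed)
    termMap <- utils::read.table(config$term_map, header = TRUE, sep = "\t",
                                 colClasses = "character")
    universe <- unique(mcols(genes)$name)
    for (dir in c("balancing", "positive")) {
      reg <- scans$group$regions
      reg <- reg[reg$direction == dir]
      ov <- overlapRegions(reg, genes)
      regGenes <- unique(unlist(ov$overlaps))
      enr <- testEnrichment(regGenes, universe, termMap, prm$min_obs)
      utils::write.table(enr, out(sprintf("enrichment_%s.tsv", dir)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, out(sprintf("enrichment_%s.tsv", dir)))
    }
  }

  prov <- list(seed = config$seed, params = prm,
               simulated = simulated,
               package_version = as.character(utils::packageVersion("driftScan")),
               r_version = R.version.string,
               timestamp_free = TRUE)
  jsonlite::write_json(prov, out("provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  paths <- c(paths, out("provenance.json"))

  ## truth-overlap summary for simulated runs: which injected intervals
  ## were recovered by a called region of matching direction
  if (simulated && length(truth$selectedIntervals)) {
    iv <- truth$selectedIntervals
    reg <- scans$group$regions
    rec <- vapply(seq_along(iv), function(i) {
      same <- reg[as.character(reg$direction) == iv$direction[i]]
      length(findOverlaps(iv[i], same, ignore.strand = TRUE)) > 0
    }, logical(1))
    utils::write.table(
      data.frame(chrom = as.character(seqnames(iv)), start = start(iv),
                 end = end(iv), direction = iv$direction,
                 recovered = rec),
      out("truth_overlap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, out("truth_overlap.tsv"))
  }

  invisible(list(genotypes = g, grm = A, pca = pca, scans = scans,
                 truth = truth, paths = paths))
}
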