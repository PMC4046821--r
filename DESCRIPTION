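Package: driftScan
Title: Drift-Model FST Genome Scans for Selection Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome scans for positive and balancing selection between
    diverged populations (e.g. taurine versus zebu cattle) from dense SNP
    genotypes. Implements a per-SNP fixation index (FST) under a pure-drift
    allele-frequency model, variable-bandwidth Epanechnikov kernel smoothing
    of the FST track along the genome, and percentile-based calling of
    high-differentiation (positive selection) and low-differentiation
    (balancing selection) regions, together with the supporting steps of a
    typical scan: call-rate and relatedness quality control, LD pruning,
    genetic relationship matrix and PCA population-structure checks,
    breed-level F-statistics, interval-annotation overlap and hypergeometric
    term over-representation. A hierarchical drift genotype simulator with
    ground-truth selected intervals makes every stage testable without
    external data. Genotypes are read from PLINK text PED/MAP files into a
    SummarizedExperiment-derived container.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
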