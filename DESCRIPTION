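Package: geascan
Title: Genome-Environment Association Scans for Landscape Genomics
Version: 0.1.0
Authors@R: person("geascan", "developers", role = c("aut", "cre"),
    email = "geascan@example.org")
Description: A pipeline for landscape-genomic genome-environment association
    (GEA) studies. Reads genotypes from VCF or PED/MAP, applies quality
    control (minor allele frequency, missingness, linkage-disequilibrium
    pruning) and encodes diploid calls as binary genotype presence/absence
    indicators; builds sample-level environmental tables from local raster
    layers or CSV files with correlation-based variable pruning; summarises
    population structure with genotype PCA and soft cluster memberships;
    fits nested logistic regressions for every genotype-indicator x
    environmental-variable pair and scores them with likelihood-ratio (G)
    and Wald statistics; converts scores to p-values, Storey q-values and
    Bonferroni-adjusted p-values; maps local spatial autocorrelation of
    genotypes (local Moran's I); and annotates candidate markers offline
    against a user-supplied GFF3. A seeded simulator with known adaptive
    loci supports testing and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    parallel,
    data.table,
    jsonlite,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
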