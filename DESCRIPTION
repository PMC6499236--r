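Package: panMSP
Title: Reconstruction of Metagenomic Species Pan-Genomes from Gene Count
    Tables
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bins co-abundant genes from shotgun-metagenomic gene count
    tables into Metagenomic Species Pan-genomes (MSPs). Gene pairs are
    compared with a robust measure of direct proportionality based on a
    median-of-ratios coefficient, a modified concordance correlation
    coefficient, detection thresholds adjusted for the proportionality
    coefficient, a structural-zero taxonomy for null counts and
    Tukey-fence outlier rejection. Seeds of directly proportional,
    co-occurring genes are built with a split-apply-combine greedy
    strategy, species core seeds are selected, and every retained gene is
    classified as core, accessory, shared core or shared accessory within
    its MSP. A seeded Poisson pan-genome simulator with full ground-truth
    export makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    BiocGenerics,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
biocViews: Metagenomics, Microbiome, Clustering, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'countMatrix.R'
    'proportionality.R'
    'seeding.R'
    'mspBuilder.R'
    'simulate.R'
    'pipeline.R'
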