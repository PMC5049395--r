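Package: bsaMapper
Title: Mapping-by-Sequencing of EMS-Induced Suppressor Mutations by
    Bulked Segregant Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and analyses mapping-by-sequencing experiments for
    EMS-induced recessive suppressor mutations in backcross F2 populations.
    Provides a synthetic-data generator (mutagenized genomes, Poisson
    crossover meioses, phenotyped pools, pooled short-read allele counts),
    the pooled allele-frequency statistic ("SNP proportion"), the EMS
    G-to-A / C-to-T spectrum filter, sliding-window linked-region
    detection, a candidate-gene funnel (non-synonymous and splice-junction
    variants against gene models), splice-defect consequence prediction
    (intron retention, cryptic splice sites), and quantification plus
    Welch/Bonferroni statistics for floral-organ abscission phenotypes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    SummarizedExperiment,
    vcfR,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, VariantDetection, Sequencing, Software
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'annotate.R'
    'bsaMapper-package.R'
    'cross.R'
    'ems.R'
    'experiment.R'
    'genome.R'
    'linked-region.R'
    'phenostats.R'
    'phenotype-sim.R'
    'pipeline.R'
    'proportion.R'
    'splice.R'
    'toy-genes.R'
    'utils.R'
    'variantio.R'
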