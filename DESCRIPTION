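Package: icemob
Title: Excision, Transfer Regulation and Paired-Read Mapping for
    Integrative and Conjugative Elements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequence-analysis toolkit for integrative and conjugative
    elements (ICEs) that excise from a host chromosome by site-specific
    recombination between attL/attR direct repeats. Provides a synthetic-data
    generator for ICE-bearing genomes and paired sequencing reads; an exact
    21-mer seed paired-read mapper with an end-to-end fragment-distance rule
    and reference-gene-normalized transcript counting; scanners for
    LysR-family TN11A binding motifs in interrupted inverted repeats,
    half-sites, and sigma-70 promoter boxes; an origin-of-transfer (oriT)
    dissection module (inverted-repeat detection, conserved-window discovery,
    deletion-series classification, essential-region intersection); and an
    att-site excision/integration model with qPCR-style relative
    quantification of the excised fraction.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, Alignment, MotifDiscovery, Coverage
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'GenomeRecord.R'
    'SimConfig.R'
    'excision-model.R'
    'genome-measures.R'
    'icemob-package.R'
    'kmer-index.R'
    'utils.R'
    'motif-scanner.R'
    'orit-analyzer.R'
    'pair-mapper.R'
    'promoters.R'
    'qpcr.R'
    'synthetic-data.R'
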