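Package: epiconcord
Title: Cross-Species Concordance Analysis of Histone Marking in Gene Orthologs
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Classifies gene orthologs across three Brassicaceae species into
    developmentally plastic versus constrained H3K27me3 marking modes and
    quantifies sequence-, expression-, synteny- and chromosome-architecture
    correlates of the two modes. Provides alignment-free k-mer promoter
    distances (Jensen-Shannon divergence and Pearson), closed-form F84
    pairwise distances, promoter 4-mer composition Z-scores, tissue-specificity
    Shannon entropy, per-synteny-block binomial enrichment tests, Hi-C contact
    strength classification with connectivity co-occurrence statistics,
    ohnolog detection via double conserved synteny, and seeded synthetic-data
    generators for every input so that the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
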