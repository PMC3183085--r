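Package: teflank
Title: Full-Site Versus Empty-Site Analysis of Heterochromatin Spreading
    from Transposable Element Insertions
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies spreading of repressive chromatin (e.g. H3K9me3,
    MeDIP methylation signal) from transposable-element insertions into
    flanking genomic DNA by comparing two strains that differ at
    insertionally polymorphic loci ("full site" versus "empty site").
    Provides strand-aware flank coverage profiles and family
    metaprofiles, the RPKM-asymmetry statistic with skewness summaries,
    distance-windowed spreading estimation with Kruskal-Wallis/Dunn
    testing, per-copy flank heatmap matrices, mappability scoring, a
    gene-impact filter for insertion-induced silencing, a genome-wide
    differential-asymmetry scan, and a fully parameterised two-line
    synthetic data generator with ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
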