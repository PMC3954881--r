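Package: arsenome
Title: Cohort-Scale Profiling of Arsenic-Related Genes in Bacterial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects, classifies and summarizes arsenic resistance and
    transformation genes (ars, arr, aio, arsM pathways) across cohorts of
    annotated bacterial genomes. Provides curated-reference homology
    screening with Smith-Waterman alignment and Karlin-Altschul E-values,
    Markov (MCL) ortholog clustering, genomic-neighborhood operon detection
    with canonical gene-order form enumeration, single-copy core-gene
    concatenated phylogenies with bootstrapped neighbor joining,
    phylogeny-ordered presence-absence distribution matrices, and
    habitat-stratified summary statistics. Includes a synthetic-cohort
    generator that plants arsenic gene clusters, scattered genes, decoys and
    universal core genes with full ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    ape,
    igraph,
    jsonlite,
    pheatmap,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
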