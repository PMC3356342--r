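Package: strandtag
Title: Stranded Tag RNA-Seq Annotation, Normalization and Antisense
    Transcript Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrated re-analysis toolkit for compact, intronless
    fungal genomes profiled with strand-specific 50-bp tag RNA-Seq, in
    the style of the Candida utilis genome/transcriptome studies.
    Merges gene models from two ab initio predictors into a consensus
    annotation with evidence-based accuracy classes, flags interrupted
    and overlapping ORF pairs caused by homopolymer indel assembly
    errors, clusters proteins into COG-style families by iterative
    triangle (3-clique) merging over all-vs-all similarity, maps 50-bp
    stranded tags by the split-read rule (up to two mismatches in the
    5' 25-mer, unique placement genome-wide), normalizes per-gene
    sense/antisense counts by each sample's upper quartile, calls
    high-expression genes and pathway-level enrichment, and discovers
    strand-specific transcribed contigs (>180 bp) classified as genic,
    antisense, or intergenic. A synthetic-data module generates a toy
    genome with planted antisense transcription, frameshifted genes,
    and two noisy predictors so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
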