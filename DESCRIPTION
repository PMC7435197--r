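Package: reachmap
Title: Reach-Based Chromatin Co-Localization and Target-Gene Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the chromatin footprint of bridging
    factors such as cullin-RING ubiquitin ligases. Converts a physical
    bridging reach into a genomic flank and extends ChIP-seq peaks into
    putative control domains; quantifies co-localization of interval sets
    against an intra-chromosomal permutation null with fold enrichment and
    empirical p-values; annotates peaks relative to transcription start
    sites and assigns proximal target genes; tests target gene sets for
    expression shifts (Wilcoxon rank-sum) and quantifies qPCR results by
    the delta-delta-Ct method; scans peak sequences for IUPAC consensus
    motifs such as the E-box with a relocation null; and generates fully
    synthetic genomes, peak sets, expression and Ct tables with planted
    structure so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
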