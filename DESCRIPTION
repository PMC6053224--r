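Package: slseeker
Title: Discovery and Characterization of Spliced-Leader Trans-Splicing from 5'-End cDNA Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for detecting spliced-leader (SL)
    trans-splicing from 5'-enriched (cap-trapper style) cDNA reads and for
    characterizing the SL RNA genes that donate the leader. Includes a
    synthetic-data generator with machine-readable ground truth (genomes
    bearing SL RNA gene families, recipient genes with pyrimidine-rich
    outrons, 5'-anchored reads), a read-filtering cascade, de novo shared
    5'-leader detection by k-mer enrichment across gene-wise read clusters,
    genome-wide SL RNA gene scanning with subtype classification, TSS and
    3'-end motif profiling, base-pair-maximization RNA folding, and per-gene
    genomic validation of trans-splicing including virtual PCR.
License: GPL-3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
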