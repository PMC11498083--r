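Package: viromics
Title: Post-Detection Processing, vOTU Clustering, and Abundance Tables for Viromes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the bespoke computational stages of a modular viromics
    workflow that sit between the external detection, alignment, and mapping
    tools: reconciliation of trimmed provirus predictions across two detection
    rounds, multi-tier filtration of predicted viral contigs by score, length,
    hallmark-gene and gene-content criteria, merging of local nucleotide
    alignments into global average nucleotide identity (ANI) with aligned
    fractions, greedy centroid clustering into species-level viral operational
    taxonomic units (vOTUs), construction of vOTU-by-sample coverage matrices
    with horizontal-coverage filtering, and quality filtration and
    concatenation of viral genome bins. Operates on the standard intermediate
    file formats (detection summary TSVs, FASTA, BLAST tabular, per-sample
    coverage tables) and ships a deterministic synthetic-fixture generator so
    every stage is testable without external binaries or databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
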