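Package: hgtrace
Title: Detection and Characterization of Horizontally Transferred Genes
    in Parasitic Plant Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested re-implementation of a screening and validation
    chain for host-to-parasite horizontal gene transfer (HGT) in plant
    transcriptomes.  Provides a taxon-aware translated-homology
    screening cascade over BLAST-style hit tables, phylogenetic
    confirmation (neighbor joining, GTR site likelihoods, RELL-based
    KH/SH topology tests, strict-clock node dating), codon-level
    selection analysis (Nei-Gojobori counting, parsimony branch counts
    pooled by lineage, per-site constraint scores), gene-structure and
    cysteine-scaffold (KNOTTIN) validation, and stage-wise RPKM
    expression profiling.  A synthetic-data module plants transfer
    events with full truth tables so the whole chain is testable
    without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
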