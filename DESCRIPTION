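Package: tagdge
Title: Tag-Based Digital Gene Expression Profiling with CATG-Anchored Tags
Version: 0.1.0
Authors@R:
    person("tagdge", "developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for NlaIII tag-based digital gene expression
    (DGE) analysis: construction of a database of 21-base tags anchored at
    CATG restriction sites in a reference transcript set, mismatch-tolerant
    tag-to-gene mapping with exclusion of multi-gene tags, transcripts-per-
    million (TPM) quantification, exact two-library count tests with
    Benjamini-Hochberg false discovery rate control, self-organizing tree
    algorithm (SOTA) and hierarchical clustering of expression profiles, and
    hypergeometric term/pathway over-representation analysis. Ships a
    synthetic-data generator (reference transcriptomes, tag libraries with
    sequencing error, annotation maps) with known ground truth so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
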