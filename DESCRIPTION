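Package: tagdge
Title: Tag-Based Digital Gene Expression Analysis
Version: 0.1.0
Authors@R:
    person("Tag", "DGE Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for SAGE-like tag-based digital gene
    expression (DGE) profiling against a de novo transcriptome. Builds a
    CATG+17 reference tag library from unigene sequences, cleans raw tag
    libraries (adapter-only reads, N-containing tags, singletons), maps
    clean 21-bp tags with at most one mismatch, counts unambiguous tags per
    gene and normalizes to tags per million (TPM), tests two-library
    differential expression with the exact Audic-Claverie statistic under
    Benjamini-Hochberg false discovery rate control, performs hypergeometric
    GO/KEGG-style term enrichment, and applies length/ORF/allelic-variant
    curation filters for detoxification gene families. Includes a synthetic
    data generator with known ground truth so the whole pipeline is testable
    without external downloads, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
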