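Package: tadcapture
Title: Integrative TAD Disruption and Promoter-Capture Hi-C Interaction
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies topologically associated domains (TADs) as conserved
    or disrupted between two cell states by gene-content equality, filters
    promoter-capture Hi-C interaction tables through a staged bait-filtering
    cascade, annotates interacting fragments with candidate cis-regulatory
    elements (SCREEN cCRE classes), and prioritizes upregulated target genes
    whose promoters form enhancer loops inside disrupted TADs.  Includes an
    insulation-score TAD boundary caller, a count-based differential
    interaction scorer, delta-Ct expression and ChIP-enrichment helpers, and
    a seeded synthetic-data generator with planted ground truth so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
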