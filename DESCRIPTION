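Package: prdscan
Title: Prion-Like Domain Detection and Functional Enrichment in Bacterial Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Proteome-wide detection of compositionally biased, prion-like
    domains (PrDs) in bacterial protein sequences using a sliding-window
    log2-likelihood-ratio (bit) score against a Q/N/S/G-rich composition model,
    with a 50-bit call threshold. Joins calls to Gene Ontology and Pfam
    annotation tables, computes enrichment factors with one-sided
    hypergeometric significance and Benjamini-Hochberg false discovery rate
    control, runs a Pfam domain-architecture census with a more-than-five
    occurrence rule, and reports multi-domain and per-organism summary
    statistics. Includes seeded generators for synthetic proteomes with
    planted prion-like regions and synthetic annotation tables with planted
    enriched terms, so the whole pipeline is testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
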