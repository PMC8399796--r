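Package: limbtrace
Title: Trio Comparative Genomics for Proband-Specific Variants, Chromosome
    Transmission Inference and Candidate-Gene Conservation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies variants specific to an affected offspring in a
    mother/sibling/proband trio, infers which paternal chromosomes were
    differentially transmitted through a per-chromosome enrichment statistic
    with chi-square significance, and prioritizes candidate genes by
    conservation and divergence: Nei-Gojobori (1986) dN/dS between ortholog
    coding-sequence pairs, missense/synonymous contrasts, orthologous-site
    conservation mapping, clade-partitioned codon conservation patterns, and
    clade branch-rate summaries on a supplied tree. Ships a seeded synthetic
    trio generator (diploid parents, whole-chromosome independent assortment,
    de novo mutations, read-depth support) so every inference stage is
    testable by parameter recovery, plus a pipeline driver that orchestrates
    simulate, classify, enrich, diverge and conserve stages into a
    machine-readable report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    vcfR,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
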