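Package: conflictscan
Title: Detection and Statistics of Conserved NTP-Dependent Conflict Systems in Prokaryotic Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A comparative-genomics toolkit for discovering conserved,
    operon-like biological conflict systems (MoxR/vWA ternary systems,
    GTPase-centric systems, peptidase-coupled systems) in prokaryotic
    genomes and for testing their association with multicellular habit.
    Provides score-density single-linkage protein clustering, conserved
    gene-neighborhood extraction and template-based classification,
    domain-architecture network statistics, positional Shannon-entropy
    screening of alignments, hypergeometric trait-enrichment and
    chi-squared positional-clustering tests, and a seeded synthetic-genome
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    phangorn,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
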