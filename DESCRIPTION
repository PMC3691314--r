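Package: srnapipe
Title: Small RNA Profiling of Deep-Sequencing Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, desk-scale re-implementation of a testis small
    RNA-seq profiling workflow. Cleans adapter-flanked Solexa-era reads
    (offset-64 qualities), collapses them to unique tags, maps tags to a
    genome with at most one mismatch and assigns each to a single small-RNA
    category through a priority cascade (miRNA, piRNA, rRNA and other
    non-coding classes, repeats, mRNA). Predicts novel miRNA hairpins with
    Mireap-style rules over a stacking-energy secondary-structure folder,
    characterizes the piRNA class (catalog matching, 1U/10A positional
    biases, the 10-nt ping-pong overlap signature, abundance concentration,
    retrotransposon target classes), predicts miRNA targets in 3'UTRs by
    seed match, duplex free energy and alignment score, and performs GO and
    pathway enrichment with the hypergeometric/Fisher test and fold
    enrichment ratio. A seeded synthetic-data generator produces genomes,
    reference catalogs, truth tables and raw reads so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
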