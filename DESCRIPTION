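Package: sixmaDyn
Title: Duplex-Aware Analysis of 6mA Methylation Dynamics Between Growth Conditions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing N6-methyladenine (6mA) dynamics in AT-rich
    polyploid genomes such as the Tetrahymena macronucleus. Classifies
    strand-resolved adenine methylation calls into symmetric, asymmetric
    (hemimethylated) and non-ApT sites, bins sites by methylation level,
    tracks per-site transitions between two growth conditions, computes
    gene-level 6mA amount statistics and their correlation with expression
    change, builds nucleosome dyad-density profiles with positioning-degree
    and periodicity statistics, and implements the DpnI/DpnII
    methylation-sensitive restriction qPCR arithmetic. A synthetic-data
    generator emulates every input format so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
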