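Package: mitocomp
Title: Comparative Analysis of Annotated Insect Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative mitogenomics of circular insect
    mitochondrial genomes: GenBank flat-file and FASTA input/output with
    origin-spanning feature locations, nucleotide composition and AT/GC
    strand-skew statistics by region, codon usage and relative synonymous
    codon usage (RSCU) under the invertebrate mitochondrial genetic code,
    start/stop-codon classification including incomplete (polyadenylation
    completed) stops, gene-junction overlap and intergenic-spacer tables,
    control-region location, gene-order encoding with breakpoint distances
    against the ancestral insect arrangement, and tRNA cloverleaf
    secondary-structure parsing with base-pair tallies. A seeded synthetic
    mitogenome generator emulates the 37-gene ancestral architecture with
    configurable composition, skews and junction geometry, and records
    ground truth for every downstream statistic so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    jsonlite
Suggests:
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
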