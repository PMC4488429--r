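Package: mitoforge
Title: Reference-Assisted De Novo Mitochondrial Genome Assembly with a
    Multiple k-mer Strategy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assembles small circular genomes (mitogenomes) from whole-genome
    shotgun paired-end reads by reference-assisted read baiting, quality-
    stratified read pools, multi-k de Bruijn unitig assembly, end-overlap
    circularization, minimal-rotation canonicalization and strand-aware
    clustering of candidate genomes, and consensus selection by identical-
    sequence support.  Also provides mitogenome annotation arithmetic on
    circular coordinates (feature lengths, intergenic spacers and overlaps,
    base composition, terminal codons) and a paired-end read simulator with
    retained ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
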