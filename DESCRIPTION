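Package: satfam
Title: Discovery, Classification and FISH Probe Design for Satellite DNA Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering large tandem-repeat (satellite DNA)
    arrays in genome assemblies, collapsing redundant detections into a
    non-redundant array catalog, clustering arrays into named repeat families
    by pairwise local-alignment similarity, annotating families against a
    repeat library, comparing family sets across assemblies, estimating
    genome abundance from raw sequencing reads, and designing short
    oligonucleotide FISH probes from the most homogeneous arrays. Includes a
    synthetic-genome generator with known ground truth so every stage is
    testable without external data, plus a reference catalog of Chinese
    hamster (Cricetulus griseus) tandem-repeat families and probes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
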