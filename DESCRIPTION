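Package: escrtscan
Title: Gene-Neighborhood Surveys of Clustered Ubiquitin-ESCRT Systems in Archaeal Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cataloguing ubiquitin and ESCRT pathway genes in sets of
    prokaryotic (especially Asgard archaeal) genomes from InterProScan domain
    annotations, measuring pairwise gene co-location within a bounded genomic
    window across a genome set, extracting synteny regions around catalogued
    genes with reciprocal-best-hit links between genomes, preparing
    concatenated multi-marker alignments with gap-threshold trimming, and
    computing sequence-derived protein properties (molecular weight, A280
    extinction coefficients, size-exclusion chromatography calibration). A
    seeded simulator of genome sets, ortholog families and alignments with
    known ground truth supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    methods,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
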