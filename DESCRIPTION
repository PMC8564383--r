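Package: figsex
Title: AGAMOUS and RAN1 Sex-Identification Markers for Fig
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis toolkit for PCR-based sex identification
    in fig (Ficus carica), a gynodioecious fruit tree. Generates synthetic
    AGAMOUS (AG) and RAN1 (HMA7) gene models and plant panels carrying the
    documented sex-linked features (a male-specific 15-bp exon-7 insertion in
    AG and a catalogue of 15 RAN1 SNP sites, 12 of them sex-discriminating),
    rediscovers those features by global alignment and panel screening,
    designs presence/absence (AG-Marker) and heterozygosity (RAN1-Marker)
    assays in silico, predicts amplicons with IUPAC-degenerate primers, calls
    sex on cultivar panels and F1 populations, and validates segregation
    ratios and marker concordance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
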