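Package: supscreen
Title: Pooled-Segregant Suppressor Mapping and Chromosome Condensation Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping spontaneous suppressor mutations in budding
    yeast by pooled-segregant whole-genome sequencing, and for scoring
    chromosome condensation in fluorescence micrographs. Includes a
    Mendelian backcross and pooled-sequencing simulator with known ground
    truth, readers and writers for pooled variant tables (VCF with pooled
    allele frequencies and a tab-separated dialect), a minimal coding-effect
    annotator (missense/nonsense/frameshift with codon-level labels),
    allele-frequency fixation filtering with cross-pool intersection, a
    synthetic DAPI-field generator, circular ROI-mask condensation
    classification, and chi-square / t-test readouts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    EBImage,
    GenomicRanges,
    igraph,
    jsonlite,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tiff,
    utils,
    vcfR,
    withr,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
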