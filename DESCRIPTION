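Package: endlesion
Title: Strand-Resolved Mapping and Classification of DNA Break Hotspots
    from END-seq Signal
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for END-seq style DNA double- and
    single-strand break mapping. Simulates strand-resolved end-capture tag
    data with planted lesions, builds binned RPKM signal tracks, calls
    peaks against a genome-wide Poisson background, filters blacklisted
    regions, forms cross-clone consensus peak sets, classifies lesions as
    symmetric (double-strand) or asymmetric (single-strand) from the
    per-strand signal log-ratio, and tests proximity to transcription
    factor binding sites and overlap with upregulated gene sets using
    hypergeometric statistics validated by a permutation oracle.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
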