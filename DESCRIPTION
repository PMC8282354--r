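Package: ipodr
Title: Genome-Wide Protein Occupancy Profiling on Circular Bacterial Chromosomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Processing and analysis of in vivo protein occupancy display
    (IPOD-HR) experiments on circular bacterial chromosomes. Converts aligned
    sequencing fragments to binned occupancy tracks, performs quantile
    normalization and periodic-spline copy-number correction, removes the RNA
    polymerase contribution from interphase occupancy with a conservative
    zero-intercept linear model, and standardizes the corrected signal as
    robust z-scores and tail p-values. Calls binding-site-scale peaks by
    continuous wavelet transform ridge detection, detects kilobase-scale
    extended protein occupancy domains (EPODs) by a seed-and-extend rule,
    summarizes condition-resolved transcription-factor occupancy with
    consensus clustering, and builds motif-discovery datasets with
    circular-permutation decoys. Includes a synthetic-data generator so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    limma,
    mgcv,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
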