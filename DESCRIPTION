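Package: UniPeakR
Title: Unified Multi-Sample ChIP-Seq Peak Calling and Quantitative
    Occupancy Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls a single consistent set of enriched regions across many
    ChIP-seq samples from kernel density estimates of 5' read-start
    profiles, with per-sample strand-shift correction, kurtosis and
    strand-correlation artifact filters, and structural filtering against
    blacklists. Produces a regions-by-samples count matrix, converts it to
    continuous occupancy scores by a negative-binomial
    variance-stabilizing transformation, and supports downstream analyses
    of high-occupancy target (HOT) regions: promoter annotation,
    occupancy-profile clustering (UPGMA and neighbor-joining),
    motif-conditioned occupancy tests, and partial least-squares models
    relating transcription-factor occupancy to gene-regulation readouts
    with leave-one-out cross-validation. Includes simulators for
    strand-asymmetric read pileups, negative-binomial count matrices and
    latent-factor regulation data so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    Rsamtools,
    rtracklayer,
    ape,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
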