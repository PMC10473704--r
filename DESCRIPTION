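Package: stomatalchrom
Title: Chromatin and Transcriptional Analyses of the Stomatal Lineage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for studying how stomatal-lineage basic
    helix-loop-helix transcription factors interact with chromatin.
    Implements per-cell Shannon transcriptional entropy and its two-level
    concentration model, ChIP-seq peak-to-gene annotation with a TSS distance
    cutoff, interval-overlap permutation testing, nucleosome-occupancy
    classification of binding sites, position-weight-matrix log-odds scanning
    and motif-presence stringency comparison, transcription-factor binding-site
    spacing analysis with Kolmogorov-Smirnov testing, expression-plus-binding
    target calling, and an S0-moderated t statistic with permutation-based FDR
    for proximity-labeling proteomics. Ships synthetic-data generators with
    planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Matrix,
    S4Vectors,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
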