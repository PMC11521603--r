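Package: defcnv
Title: Copy Number Variation Analysis of Multicopy Gene Families from
    Read Depth and Droplet Digital PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-focused copy number variation (CNV) analysis for
    multicopy gene families such as the beta-defensins, from short-read
    whole-genome sequencing and droplet digital PCR (ddPCR). Estimates
    diploid copy numbers from per-region read counts by reference-gene
    normalization, calls deletions and duplications with expected-copy
    scaled thresholds, detects genes co-varying on shared copy-number
    variable segments, quantifies ddPCR copy numbers via Poisson
    partition statistics, and correlates copy number with expression
    (gene dosage). Includes a fully seeded synthetic cohort generator
    emulating the statistical structure of such studies, and a
    one-call pipeline producing auditable tabular outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    igraph,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
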