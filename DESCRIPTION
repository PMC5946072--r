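Package: m6aging
Title: MeRIP-Seq m6A Profiling and Age-Cohort RNA Regulation Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling N6-methyladenosine (m6A) RNA modification
    from MeRIP-seq fragment counts and relating methylation to transcript
    fate in two-cohort (young versus old) designs. Provides window-based
    m6A site calling from IP versus input libraries with a
    dispersion-aware enrichment test, DRACH-derived motif classification
    (GGACU/GACU/ACU/GAC), FPKM quantification, biotype and motif tallies,
    cohort site overlap, metagene profiles around translation start and
    stop codons, ECDF/Kolmogorov-Smirnov comparison of expression fold
    changes stratified by methylation and RNA-binding-protein target
    status, mRNA half-life estimation from actinomycin-D RT-qPCR time
    courses via the delta-delta-Ct method, and Z-ratio differential
    expression for miRNA microarrays. A seeded synthetic-data generator
    emulates the full study design so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    dplyr,
    jsonlite,
    methods,
    readr,
    rtracklayer,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
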