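Package: corepic
Title: Core Promoter Architecture and Preinitiation Complex Occupancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide analysis of general transcription factor
    occupancy at human core promoters. Implements robust scaling of tiling-array
    ChIP/input log2 ratios (one-step Tukey biweight), probeset promoter scores,
    threshold-run peak calling at graded stringencies, TSS-aligned
    availability-corrected binding profiles, TSS-anchored IUPAC scanning for the
    canonical core promoter elements (TATA, TATA-like, BREu, BREd, INR, DPE),
    occupancy-expression statistics (sliding-window correlation, expression
    quantile tables, bootstrap two-sample Kolmogorov-Smirnov test), TFIIB/NC2
    ratio curves with dominated-gene selection, motif combination and
    co-occurrence counting, and TSS shape classification from CAGE-like tag
    vectors. A seeded synthetic promoter-cohort generator with plant-then-scrub
    motif fixtures emulates the structure of promoter tiling-array studies for
    testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
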