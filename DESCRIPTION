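Package: silencerscan
Title: Proto-Silencer Detection and Binding-Site Conservation in Budding Yeast
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A pipeline for analysing the genomic architecture of
    silencer-like elements in Saccharomyces. Builds position weight
    matrices from counts or aligned sites, computes exact match p-values
    by dynamic programming over the discretised score distribution, scans
    intergenic regions on both strands, detects proto-silencers (Rap1 and
    Abf1 binding sites co-occurring within a configurable window),
    measures cross-species binding-site conservation over
    reciprocal-best-hit orthologous regions with a chi-squared comparison,
    and computes per-transcription-factor motif frequencies from
    ChIP-style binding tables. Includes a truth-known synthetic
    multi-species cohort generator for end-to-end calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
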