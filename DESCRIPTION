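Package: poremod
Title: De Novo Detection of DNA Base Modifications from Nanopore Signal
    Comparisons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects DNA base modifications de novo from Oxford Nanopore
    sequencing by comparing per-reference-position distributions of raw
    current signals between a modified and a matched unmodified sample.
    Provides alignment-guided correction of basecalling indel errors by
    event re-segmentation, median-based per-read signal normalization,
    per-position two-sample Kolmogorov-Smirnov testing (with Mann-Whitney
    U and Student's t alternatives), weighted Stouffer and Fisher
    combination of neighboring p-values, neighborhood-based non-redundant
    ranking of candidate sites, a pore-model-driven signal simulator with
    configurable modification scenarios, and percentile-based
    precision/recall evaluation of ranked site lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    vctrs,
    ggplot2,
    generics,
    stats,
    utils,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
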