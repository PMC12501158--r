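Package: predscreen
Title: Transposon Screens, Population Bottlenecks, and Phase Variation
    Under Bacterial Predation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for pooled transposon-insertion (Tn-seq)
    screens of bacterial prey populations under protozoan predation.
    Quantifies per-position insertion counts into window- and
    feature-based count matrices with low-coverage filtering, calls
    predation-enriched loci by top-quantile log2 fold change and
    principal component summaries, brackets the consumed-cell fraction
    with binomial-survival/multinomial-resampling bottleneck
    simulations including jackpot-event risk, scans coding sequences
    for homopolymer repeats and calls frameshift-inducing repeat-length
    changes with premature stop codons across ortholog sets, and
    provides phenotype statistics for filamentation and competition
    assays. A synthetic-data generator with recorded ground truth
    emulates every input the pipeline consumes.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
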