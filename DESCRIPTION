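Package: circage
Title: Spatial, Sex and Age Specificity Analysis of circRNA Back-Splice Junction Expression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for circular RNA (circRNA) expression quantified by
    back-splice junction read counts across a multi-region, two-sex, two-age brain
    design. Provides readers for CIRI2-style junction tables, gene models and count
    matrices; genomic-context classification and tolerance-based matching of circRNA
    sets; a five-rule expression-filter cascade; median-of-ratios size-factor
    normalization; one-vs-rest spatial, sex-biased and age-biased screens by Welch
    t-tests and a label-permutation null; simplified weighted co-expression modules
    (soft-threshold adjacency, topological overlap, eigengenes); circRNA/host-mRNA
    Pearson correlation classification; log-space hypergeometric enrichment; and a
    negative-binomial synthetic-data generator with full ground truth emulating the
    8-region x 2-sex x 2-age design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    DESeq2,
    withr,
    optparse
Config/testthat/edition: 3
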