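Package: lncforge
Title: Building and Profiling an Extended Long Non-Coding RNA Gene Atlas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assembling an extended long non-coding RNA (lncRNA) gene
    catalogue from multiple annotation sources and for profiling it with bulk
    RNA-seq expression data. Annotation sources are ranked by CAGE support of
    their transcript 5' ends and aggregated sequentially, rejecting gene models
    with same-strand single-base overlap against the growing catalogue. Each
    lncRNA gene is classified positionally against its closest protein-coding
    gene (genic/intergenic; divergent, convergent, same-strand; containing,
    nested, overlapping; exonic/intronic), small-RNA host lncRNAs are detected
    by containment, tissue specificity is scored with the tau index, and
    lncRNA:protein-coding co-expression is tested with Spearman correlation
    under Benjamini-Hochberg control together with Fisher enrichment of
    genomic configurations. A seeded synthetic-data generator plants known
    overlap fractions, CAGE support, pair configurations, tau profiles and
    correlated pairs so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
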