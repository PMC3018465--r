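Package: meiospec
Title: Meiocyte RNA-Seq Normalization, Differential Expression and
    Meiosis-Specificity Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying meiosis-specific genes from three-tissue
    (meiocyte, anther, seedling) bulk RNA-Seq read counts. Implements
    reads-per-million normalization with binomial pseudo-replicate splitting,
    per-gene one-way ANOVA with pooled pairwise contrasts and
    Benjamini-Hochberg false discovery rate control, fold-change filtering, a
    two-criterion tissue-specificity classifier with anther-wall exclusion,
    Venn partitioning of significant gene sets, and genomic summaries of the
    chromosome II mitochondrial-insertion block and of transposable-element
    expression by superfamily and chromosomal position. A seeded synthetic
    count generator with planted gene classes and genome structure provides
    ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    emmeans,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
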