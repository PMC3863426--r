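Package: duplirep
Title: Gene Duplication Age, Copy-Number Variability and DNA Replication Timing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links the evolutionary age of gene duplicates to copy-number
    variability and DNA replication timing. Assigns each protein-coding gene a
    duplication age class (phylostratum) from annotated gene-family trees in
    NHX format, classifies genes as copy-number variable from a gene-by-
    individual copy-number matrix, converts multi-sample replication-timing
    probe log-ratios into a per-gene order of replication, stratifies genes
    into pericentromeric, subtelomeric and interstitial regions, and runs the
    nonparametric test battery (chi-squared enrichment, Wilcoxon rank-sum,
    Spearman rank correlation, fold enrichment) tying the layers together. A
    synthetic-data generator plants known duplication ages, CNV labels and a
    monotone age-to-replication-timing effect so that every stage is
    verifiable by planted-truth recovery.
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
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
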