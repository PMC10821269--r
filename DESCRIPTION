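Package: capcnv
Title: Absolute Gene Copy Number from Targeted Long-Insert Sequence Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies absolute gene copy numbers from hybridization-capture
    coverage of large genomes, where whole-genome sequencing is impractical.
    Provides tiled 80-nt bait design over padded target regions with melting
    temperature and genome-hit filtering, per-region capture coverage
    statistics (mean target-base depth, normalized coverage, enrichment
    factor, sensitivity), selection of high-confidence single-copy internal
    standards from log-normalized coverage and single-copy classification,
    a from-scratch trimmed-mean-of-M-values (TMM) between-sample
    normalization, copy-number estimation by geometric-mean scaling against
    internal standards with a gene-resampling bootstrap cross-estimator,
    downstream inferential tests (two-way ANOVA, Wilcoxon, Tukey HSD,
    Welch t, Pearson), a qPCR validation arm (sigmoidal threshold-cycle
    calling and standard-curve absolute quantification), and a
    negative-binomial capture simulator with known copy-number truth for
    verifying the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    car,
    edgeR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
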