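Package: tinscope
Title: Transcriptome Instability Scoring from Exon Array Splicing Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies transcriptome instability (TIN) from probe-level exon
    microarray intensities. Implements the FIRMA approach to exon-level
    alternative splicing: inter-chip quantile normalization, additive
    gene-level models fitted by Tukey median polish, and per-exon splicing
    scores taken as probeset medians of the model residuals. Sample-wise
    TIN-estimates summarize aberrant exon skipping and inclusion counts
    beyond dataset-wide percentile thresholds, on a log2 scale relative to
    the dataset average. Association between TIN-estimates and splicing
    factor gene expression is tested with Pearson correlations against
    permutation and random-gene-set empirical null distributions, within
    single datasets and in pooled (pan-cancer) mode. A synthetic exon-array
    generator with planted aberrant splicing coupled to a latent splicing
    capacity makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
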