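Package: splicearray
Title: Splicing-Sensitive Microarray Analysis and Genetic-Interaction
    Enrichment for Budding Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for genome-wide splicing phenotyping in Saccharomyces
    cerevisiae with two-color splicing-sensitive microarrays (terminal exon,
    intron, and exon-exon junction probes per intron-containing gene),
    producing per-gene feature log2 ratios and Intron Accumulation Indices,
    defect calls, and average-linkage/uncentered-Pearson clustered profiles.
    Companion tools integrate synthetic genetic array hit lists, quantitative
    E-MAP genetic-interaction scores, and directed-genetics calls into a
    negative-interaction gene set, and test protein complexes and GO-slim
    processes for hypergeometric enrichment with empirical min-p resampling
    or Bonferroni family-wise correction. A seeded synthetic-data module
    emulates the screens and array experiments with planted ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
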