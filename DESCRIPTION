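Package: dcnet
Title: Differential Co-Expression Network Analysis for Two-Condition
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated workflow for mining disease-associated genes from
    two-condition (e.g. normal vs cancer) expression matrices: SAM-style
    differentially expressed gene selection with balanced label permutations
    and a permutation false discovery rate, per-condition hard-threshold
    Pearson co-expression networks with topology diagnostics,
    differential-link detection with a Fisher-z permutation test, hub-gene
    ranking in the differential subnetwork, and module detection by
    hierarchical clustering of (generalized) topological overlap. Includes a
    latent-factor synthetic-data generator with planted ground truth so
    every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
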