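Package: connectomotif
Title: Network-Motif Analysis of Structural Connectomes by Singular Value
    Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Decomposes cohorts of white-matter structural connectivity
    matrices (tractography streamline counts on a fixed cortical
    parcellation) into orthonormal network motifs via singular value
    decomposition, and relates per-subject motif prevalences to behavioral
    performance with rank-based nonparametric tests (Spearman correlation
    and Mann-Whitney U, Bonferroni-corrected). Includes readers and writers
    for delimited connectivity matrices and cohort manifests, a behavioral
    performance module for sentence-comprehension accuracy, edgewise
    group-change tests, motif reporting (top regions, signed edge lists,
    regression pairs), and a synthetic-cohort generator with planted
    low-rank motifs for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
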