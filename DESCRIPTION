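Package: topoent
Title: Degree-Based Topological Indices and Graph Entropy for the
    Beryllonitrene Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes degree-based topological indices (Randic family, atom-bond
    connectivity, geometric-arithmetic, Zagreb, hyper-Zagreb, forgotten, augmented
    Zagreb and redefined Zagreb indices), index-weighted Shannon graph entropies,
    and logarithmic/power regressions of entropy on index for the beryllonitrene
    BeN4(m,n) lattice and for arbitrary simple graphs supplied as edge lists.
    Two evaluation modes are first class: canonical values obtained from the
    degree-based edge partition, and as-published closed-form polynomials in the
    unit-cell counts (m, n), together with a discrepancy audit between the two.
    Includes seeded graph and regression-data generators so every stage is
    testable without external input, and a reproduction driver that re-derives
    the reference numeric tables and flags cell-level agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
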