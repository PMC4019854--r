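Package: connrepro
Title: Reproducibility Analysis of Structural Brain Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Test-retest reproducibility analysis for structural brain networks
    built from streamline-count connectivity matrices. Provides constant-density
    cumulative thresholding and binarization, seven binary undirected graph
    metrics (mean clustering coefficient, characteristic path length, largest
    connected component size, assortativity, global and local efficiency, and
    the rich-club coefficient), graph curves over density (and over degree
    level for the rich club), edge-wise Dice topological similarity, one-way
    random-effects intraclass correlation (ICC) reproducibility curves, and a
    permutation test on the area between group mean curves in the style of
    functional data analysis. A seeded synthetic test-retest connectome
    generator with controllable between-subject and within-subject variance
    and group effects supports end-to-end simulation studies without imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
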