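Package: nmaconnect
Title: Connectedness and Indirectness of Evidence Networks in Network
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds treatment evidence networks from arm-level tables, wide
    one-row-per-study treatment matrices, or plain edge lists, and tests
    their connectedness with matrix methods from graph theory: adjacency
    matrix construction, walk-count powers, the indirect connection matrix
    (transitive closure), the shortest-path distance matrix quantifying the
    indirectness of each treatment comparison, connected-component
    detection, and block-diagonal collection of matrices for presentation.
    Includes labelled CSV/TSV readers and writers, programmatic fixtures
    for worked example networks, a seeded random-network generator with
    planted components, and a command-line interface that warns when an
    evidence network is disconnected.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
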