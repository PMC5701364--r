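Package: themesort
Title: Theme Elicitation from Multi-Sorter Card Sorts of Qualitative Excerpts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Combines the card-sort piles of several lay sorters into a
    shared set of thematic groups. Pairwise similarity scores (the number
    of sorters co-assigning two excerpts) define a weighted co-occurrence
    network whose edge lengths are conceptual distances (1/score);
    communities are detected by iterative removal of the highest
    edge-betweenness tie with a weighted-modularity cut, key excerpts per
    theme are surfaced via within-cluster closeness and bridging
    betweenness, and per-sorter pile-preservation diagnostics flag
    divergent perspectives. A planted-partition simulator with
    merge/split/noise perturbations supports method evaluation via the
    adjusted Rand index.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    jsonlite,
    mclust,
    igraph,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
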