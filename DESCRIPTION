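Package: klnrank
Title: Influential-Node Ranking in Networks via Neighborhood Kullback-Leibler Divergence
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies influential nodes in undirected networks by measuring the
    information-entropy loss a node's removal inflicts on its neighborhood.  For
    each node the degree-proportional dissemination probabilities over its
    neighbors (the real distribution) are compared, via Kullback-Leibler
    divergence, against the distance- and degree-weighted probabilities that
    remain after the node is removed (the fitting distribution); K-shell-weighted
    divergences plus degree give a damage-influence score, and the final KLN
    importance adds the square-rooted damage influence of the one-hop
    neighborhood.  Ships classical baselines (degree, K-shell, eigenvector,
    PageRank), a discrete-time SIR spreading simulator used as the ground-truth
    influence oracle, ranking-comparison metrics (Kendall tau, top-N overlap,
    capacity-by-rank roughness, management tiers), reproducible random-graph
    generators, and a command-line interface.  All result types are tibbles with
    broom-style tidy()/glance() methods and ggplot2 autoplot() visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
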