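Package: mowoats
Title: Multi-Objective Whale Optimization with Tabu Search for Clustering Expression Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Centroid-based clustering of gene-expression matrices by a hybrid
    multi-objective whale optimization algorithm with tabu-search memory
    (MOWOATS). Candidate clusterings are scored simultaneously on the Xie-Beni
    index, overall cluster deviation and the Simple Silhouette Index; mutually
    non-dominated solutions are kept in a bounded Pareto elite list that guides
    the swarm, with crossover phases triggered by stagnation. Includes
    minimum-order rank (Spearman) distances for shape-based similarity,
    partition-parallel objective evaluation, cluster validation (full
    Silhouette, Davies-Bouldin, Dunn, F-measure), Eisen-style cluster-ordered
    heatmap export, a synthetic expression-data generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    parallel,
    jsonlite,
    yaml,
    optparse
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
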