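Package: entropin
Title: Signalling Entropy Rates on Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes global signalling entropy rates by integrating gene
    expression profiles with protein interaction networks (PINs) under the
    mass-action principle. Provides the equilibrium entropy rate (stationary
    distribution weighted local entropies scaled by the maximum entropy
    rate) and the non-equilibrium entropy rate (mean normalized local
    entropy), edge perturbation null models (add, remove, flip, rewire) for
    probing the sensitivity of both measures to network topology,
    edge-reliability scoring by topological (Jaccard, Czekanowski-Dice,
    inverse log-weighted), semantic (Resnik, Lin, Jiang-Conrath, Schlicker,
    Wang) and STRING combined-score methods with threshold filtering, and
    between-/within-class significance analysis for comparing entropy rates
    across biological conditions. A synthetic-data module generates
    scale-free interactomes, two-class expression matrices (including
    dual-knockout designs), toy ontologies with gene annotations, and
    edge-reliability score tables so the whole pipeline can be exercised
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
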