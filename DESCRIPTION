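Package: netgame
Title: Spatial Social-Dilemma Games on Networks and Game Centrality
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates repeated two-strategy social-dilemma games (prisoner's
    dilemma, hawk-dove and free-form 2x2 payoff matrices) on arbitrary
    weighted undirected networks, with best-takes-over, Fermi and
    proportional imitation update rules, synchronous or semi-synchronous
    scheduling, optional edge weights read as per-round play probabilities,
    and user-registered plugin rules. Implements game centrality: the
    defector fraction, averaged over a trailing window after drift
    convergence, reached when a single node, a linked node pair, or a node
    set starts as the only defectors in an otherwise cooperating network,
    with replicate batching until the standard error of the estimate falls
    below a fluctuation threshold. Includes a Pajek network reader/writer,
    synthetic graph generators, a residue-interaction-network builder from
    protein 3D coordinates (heavy-atom contacts within a distance cutoff,
    inverse mean contact distance as edge weight), and the rank-association
    and comparison statistics (Goodman-Kruskal gamma, binned two-sample
    chi-square, dependent-correlation comparison) used to relate game
    centrality to classical centrality measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    bio3d,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
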