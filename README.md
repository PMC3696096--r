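# netgame

Spatial social-dilemma games on networks, and **game centrality**: a
dynamic centrality measure that scores each node by its power to break
the cooperation of everyone else.

## The problem

In a spatial game every agent sits on a node of a contact network,
plays a symmetric 2x2 game with each neighbor every round, and then
imitates a successful neighbor. For the prisoner's dilemma with payoffs
`T > R > P > S` (temptation, reward, punishment, sucker), defection is
individually tempting but collectively ruinous, and whether cooperation
survives depends on the network and on *where* defection starts. Game
centrality quantifies that: set every node to cooperate except node
*i*, which defects; run the repeated game until the defector fraction
drifts by less than 0.01 over 50-round windows; average the defector
fraction over the final 50 rounds; and average replicates until the
standard error falls below 0.01. The result, GC\_i in [0, 1], is high
for nodes whose lone defection cascades through the network and ~0 for
nodes the network heals. The same protocol applies to linked pairs
(edge GC) and arbitrary node sets (set GC — e.g. "30 random party
hubs"). It is a tool for finding influential nodes in social networks,
protein-protein interaction networks, and residue interaction networks
of protein structures, where "cooperation" models the integration of
the system.

The package provides:

* a simulation engine for any symmetric 2-strategy game on any
  weighted undirected network (Pajek I/O), with best-takes-over,
  Fermi, and proportional update rules, synchronous and
  semi-synchronous schedules, optional edge weights as play
  probabilities, and plugin rules (`register_rule()`);
* node / edge / set game centrality with the drift and fluctuation
  stopping thresholds, replicate batching, and ranked GC tables;
* a protein-structure-network builder (heavy-atom contacts within
  4 Å, inverse mean contact distance as weight);
* the validation statistics: Goodman-Kruskal gamma (with SE and
  p-value), binned two-sample chi-square for GC distributions, and
  Williams' test for dependent correlations;
* a YAML-configured runner (`run_from_config()`) and a thin CLI
  (`inst/cli/netgame.R`) with `run`, `gc`, `gc-edge`, `gc-set`,
  `gc-sample`, `psn-build`, `stats-gamma`, `stats-chi2` subcommands.

## Worked example

```r
library(netgame)

net <- karate_network()   # Zachary's karate club, 34 nodes, 78 edges
tab <- gc_table(net, m = game_preset("pd_canonical"), seed = 1)
head(tab, 5)
#>   target        gc sem replicates mean_rounds converged rank
#> 1      3 1.0000000   0         10         101      TRUE    1
#> 2     33 1.0000000   0         10         101      TRUE    1
#> 3      1 0.4705882   0         10          99      TRUE    3
#> 4      2 0.4705882   0         10         100      TRUE    3
#> 5     34 0.4705882   0         10          99      TRUE    3
```

Nodes 3 and 33 can each single-handedly convert the whole club to
defection (GC = 1); the instructor (node 1) and the president
(node 34), with node 2, convert a stable 47% of it and tie for the
next rank. `sem = 0` with 10 replicates means the runs were tie-free
and deterministic, so batching stopped at the minimum replicate
count. The five top-GC members are exactly the five highest-degree
members of the club.

Edge and set variants:

```r
game_centrality_edge(net, "1", "2")           # a linked pair defects
sampled_set_gc(net, node_labels(net), size = 5, samples = 100, seed = 1)
```

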