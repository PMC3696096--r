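---
title: "Game centrality: measuring a node's power to break cooperation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Game centrality: measuring a node's power to break cooperation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netgame)
```

## The model

A spatial social-dilemma game places one agent on every node of a
contact network. Each round, every agent plays a symmetric 2x2 game
with each of its neighbors and accumulates the payoffs: `R` for mutual
cooperation, `P` for mutual defection, `T` (temptation) to a defector
meeting a cooperator, who receives `S`. In the canonical prisoner's
dilemma `T > R > P > S`, so defection dominates pairwise even though
mutual cooperation pays more — cooperation can persist only through the
network ("network reciprocity"). After the round, agents revise their
strategies by imitation, and the process repeats.

`netgame` simulates this loop on arbitrary weighted undirected networks
and uses it to define **game centrality (GC)**: start every node
cooperating except a chosen node (or linked pair, or node set) which
defects, iterate the game to convergence, and record the defector
fraction averaged over the last 50 rounds. A node of high GC can, on
its own, convert a cooperating network to defection; a node of low GC
is absorbed back into cooperation. GC is a *relative* measure: it is
meaningful for comparing nodes of the same network under the same game
settings, not across settings.

## Update rules and schedules

Three replicator-type imitation rules are built in; user rules can be
registered as plugins.

* **Best-takes-over** (`update_best_takes_over`): the focal node adopts
  the strategy of the highest-payoff member of its closed neighborhood
  (itself included). Ties among maximal members are broken uniformly at
  random — the rule's only stochasticity. Including the focal node
  makes uniform states absorbing; random tie-breaks are what lets
  otherwise deterministic runs split between outcomes (this is how a
  linked pair can end a "strike" in only a fraction of replicates).
* **Fermi rule** (`update_fermi`): pick one neighbor *j* uniformly;
  adopt its strategy with probability
  $1/(1+\exp((\Pi_i-\Pi_j)/K))$. The pairwise-comparison form is the
  field's standard; the noise `K` (default 0.1, configurable in
  `rule_spec()`) sets how sharply payoff differences are felt. The rule
  name alone does not pin down a functional form, so the form and the
  default are package choices, surfaced in every run manifest.
* **Proportional update** (`update_proportional`): pick one neighbor
  uniformly; if it scored higher, imitate with probability
  $(\Pi_j-\Pi_i)/(\max(k_i,k_j)\,(\max(T,R)-\min(S,P)))$ — the
  replicator convention normalized by the largest achievable payoff
  difference. Downhill imitation never occurs.

Updates are **synchronous** (all nodes revise simultaneously against
the pre-step payoffs) or **semi-synchronous**: each node participates
in a given round with independent probability `q` (default 0.5). `q`
interpolates between synchronous (`q = 1`) and nearly asynchronous
dynamics; like `K`, it is a package default, not a published constant.

Edge weights are ignored by default. With `weight_mode = TRUE` a
weight is read as the probability that the edge's game is played that
round, drawn once per edge so both endpoints see the same event.
Weights above 1 (as produced by inverse-distance structure networks)
are clamped to probability 1 with a warning; the case-study analyses
do not use weight mode, so the clamp only affects an optional path.

Payoffs are accumulated, not degree-normalized, the standard
spatial-game convention (degree normalization would be a different —
also defensible — measure, and is deliberately not silently mixed in).

## Stopping rules

Two thresholds, both 0.01 by default and both exposed in
`convergence_spec()`, control an estimate:

* **Drift threshold** (per replicate): rounds continue until the mean
  defector fraction of the last 50 rounds differs by less than 0.01
  from the mean of the 50 rounds before. The published description
  ("the mean changed less than 0.01 in the last 50 rounds") does not
  give a formula; the difference of two adjacent non-overlapping
  window means is the operationalization chosen here. It needs at
  least 100 recorded rounds, which also carries every run past the
  initial transient. A `max_rounds` cap (default 10,000) turns
  never-settling dynamics (square-lattice games are the classic case)
  into a flagged non-converged estimate rather than an error.
* **Fluctuation threshold** (across replicates): each replicate
  contributes the windowed mean of its own trace; replicates are added
  in batches of 10 (replicate *r* is seeded `seed + r`) until the
  standard error of those values drops below 0.01, between
  `min_replicates` (10) and `max_replicates` (10,000). For tie-free
  best-takes-over runs all replicates are identical, the SEM is
  exactly 0, and batching stops at the minimum — which is why sweeps
  with the deterministic rule are cheap.

The 50-round window balances averaging accuracy against convergence
speed; GC remains comparable when computed with other window lengths,
but all defaults here follow the published protocol.

## What the synthetic generators emulate — and what they do not

`make_network()` produces the arenas the analytic test suite reasons
about exactly: complete graphs (a lone defector's payoff `T(n-1)`
beats every cooperator's `R(n-2) + S`, so defection fixates in one
step), stars (a hub with `k >= 4` leaves earns at least `3R = 9 > T`,
so a defecting leaf is healed while a defecting hub converts everyone),
rings, grids, Erdős–Rényi and Barabási–Albert graphs. These fixtures
make the engine's correctness checkable against enumeration, and the
Erdős–Rényi ensemble drives the trace-level cross-check against a
naive reference simulator.

They do not emulate the degree heterogeneity, modularity, or weight
structure of real interactomes and sociograms. Passing the analytic
suites therefore demonstrates that the *mechanics* (payoff accounting,
update rules, schedules, stopping rules) are right; conclusions about
real networks still require the real networks, which is why the
package validates against the bundled Zachary karate club network and
treats the strike sociogram and the yeast interactome as optional
external fixtures (`inst/extdata/external/README.txt`).

## Numerical choices

* Exact ties in best-takes-over are detected by floating-point
  equality with the maximum. The canonical payoff set (3, 0, 6, 1)
  keeps all accumulated payoffs exactly representable, so ties are
  exact; fractional payoff sets (e.g. `T = 3.1`) make tie detection
  sensitive to summation order in principle, which the engine keeps
  fixed (edge-table order).
* The RNG contract is part of the engine's definition: edge-firing
  draws in edge order, then participation draws in node order, then
  per-node rule draws in node order. Any independent implementation
  following it reproduces traces bit-for-bit from the same seed, which
  the test suite exploits.
* Uniform states are absorbing under all built-in rules, so the engine
  stops simulating once one is reached and fills the remaining rounds;
  plugin rules never take this shortcut (a plugin may leave uniform
  states).
* Sampled-set analyses stride sample seeds by 100,000 so replicate
  streams never overlap across samples.

## Statistics

Rankings produced by GC sweeps carry many ties, so rank association is
measured with the Goodman–Kruskal gamma, `(C - D)/(C + D)` over
concordant and discordant pairs, ties excluded. The asymptotic
standard error and the gamma-is-zero test are the standard
Goodman–Kruskal estimators (the source analyses name the test but not
the estimator). GC distributions from sampled node sets are compared
with a two-sample chi-square on 10 equal-width bins over [0, 1],
pooling adjacent bins until every expected count reaches 5 — the
binning is likewise a package choice, recorded here because only the
qualitative statistic was published. `compare_dependent_cors()`
(Williams' t) covers the "is predictor A significantly better
correlated than predictor B" comparison for correlations sharing a
variable.

## Protein structure networks

`build_psn()` turns a 3D structure into a residue interaction network:
heavy-atom contacts within 4.0 Å (0.4 nm), excluding the covalent
backbone peptide bond C(i)–N(i+1); an edge's weight is the inverse of
the arithmetic mean over its *qualifying* (within-cutoff) atom-pair
distances, so every weight is at least `1/cutoff`. Averaging over
contact pairs rather than all atom pairs, and restricting to heavy
atoms, are both stated assumptions: the construction recipe's "average
distance between amino acid residues" is ambiguous on the first point
and silent on hydrogens, and both choices are visible function
arguments. Residues with no contacts drop out of the network.
Alternate locations resolve to the highest-occupancy copy (first on
ties); HETATM records are ignored.

## Problem sizes

The default suites run complete graphs to `n = 20`, the 34-node karate
club, trace cross-checks on 200 random graphs of up to 12 nodes, and
stochastic-rule estimates on 8-node graphs — sizes at which the
enumerable oracles stay exact and a full run of the suite completes in
well under a minute per component on a single core. Larger networks
(the 2,444-node interactome) use the same code paths; only the
replicate counts grow.

## Known limitations

* Only pairwise games: no public-goods (group) interactions, no
  rock–paper–scissors or other >2-strategy games.
* No mutation/exploration noise and no coevolving topology.
* The "inverse" measure (a lone cooperating pair in an all-defecting
  network) and GC of motifs/cliques/communities are not implemented.
* Directed games are out of scope; Pajek `*Arcs` sections are
  symmetrized on input, a choice the reader should be aware of when
  feeding directed data.
* GC values depend on the payoff set, rule, schedule, and network;
  they are comparable within one configuration only.

## A worked example

```{r example}
net <- karate_network()
tab <- gc_table(net, m = game_preset("pd_canonical"), seed = 1)
head(tab, 5)
```

Nodes 3 and 33 share the top rank, with nodes 1 (the instructor), 2,
and 34 (the president) tied just below — the five highest-degree
members of the club.
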