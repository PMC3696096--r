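pd <- game_preset("pd_canonical")

test_that("drift test compares adjacent trailing windows", {
  cs <- convergence_spec(window = 50)
  expect_true(drift_converged(rep(1, 100), cs))
  # linear ramp 0 -> 1 over 100 rounds: |0.75 - 0.25| = 0.5 >= 0.01
  expect_false(drift_converged(seq(0, 1, length.out = 100), cs))
  expect_false(drift_converged(rep(1, 60), cs))   # insufficient history
  cs5 <- convergence_spec(window = 5)
  expect_true(drift_converged(c(0, 1, rep(0.5, 10)), cs5))
  expect_error(convergence_spec(window = 0))
  expect_error(convergence_spec(min_replicates = 20, max_replicates = 10))
})

test_that("node GC matches the complete-graph and star oracles", {
  for (n in c(3, 7, 12, 20)) {
    kn <- make_network("complete", n = n)
    est <- game_centrality_node(kn, "n1", seed = n)
    expect_equal(est$gc, 1.0)
    expect_true(est$converged)
    expect_equal(est$sem, 0)
    expect_equal(est$replicates, 10)   # deterministic: stops at minimum
  }
  for (k in c(4, 6, 9)) {
    st <- make_network("star", leaves = k)
    expect_equal(game_centrality_node(st, "n1", seed = 1)$gc, 1.0)  # hub
    expect_equal(game_centrality_node(st, "n2", seed = 1)$gc, 0.0)  # leaf
  }
  # hub defection also fixates for tiny stars (k >= 2)
  st2 <- make_network("star", leaves = 2)
  expect_equal(game_centrality_node(st2, "n1", seed = 1)$gc, 1.0)
  expect_error(game_centrality_node(make_network("complete", n = 3), "zzz"),
               "unknown node")
})

test_that("edge GC requires adjacency and counts both seeds at round 0", {
  k5 <- make_network("complete", n = 5)
  expect_equal(game_centrality_edge(k5, "n1", "n2", seed = 1)$gc, 1.0)

  path <- network(c("a", "b", "c"), from = c(1, 2), to = c(2, 3))
  est <- game_centrality_edge(path, "a", "b", seed = 1)
  expect_equal(est$gc, 1.0)  # b earns T = 6, maximal; defection fixates
  expect_error(game_centrality_edge(path, "a", "c"), "not adjacent")

  tr <- run_game(path, initial_strategies(path, c("a", "b")), pd,
                 rounds = 1, seed = 1)
  expect_equal(tr$defector_fraction[1], 2 / 3)
})

test_that("set GC generalizes node GC and saturates at the full set", {
  k6 <- make_network("complete", n = 6)
  expect_equal(game_centrality_set(k6, node_labels(k6), seed = 1)$gc, 1.0)
  expect_error(game_centrality_set(k6, character()), "nonempty")

  g <- random_net(10, 0.35, seed = 21)
  a <- game_centrality_set(g, "n3", seed = 5)
  b <- game_centrality_node(g, "n3", seed = 5)
  expect_equal(a$gc, b$gc)
  expect_identical(a$values, b$values)
})

test_that("stochastic-rule estimates keep batching until the SEM threshold", {
  g <- random_net(8, 0.5, seed = 31)
  est <- game_centrality_node(g, "n1", spec = rule_spec("fermi"),
                              cs = convergence_spec(max_replicates = 4000),
                              seed = 11)
  expect_true(est$sem < 0.01 || est$replicates == 4000)
  if (est$converged) expect_lt(est$sem, 0.01)
  expect_gte(est$gc, 0)
  expect_lte(est$gc, 1)
})

test_that("automorphism-equivalent nodes receive equal GC", {
  nets <- list(make_network("ring_lattice", n = 6),
               make_network("grid", rows = 2, cols = 4),
               make_network("complete", n = 5))
  for (net in nets) {
    gcs <- vapply(seq_len(n_nodes(net)), function(i)
      game_centrality_node(net, i, seed = 3)$gc, 0)
    for (orb in brute_orbits(net)) {
      expect_lt(diff(range(gcs[orb])), 1e-12)
    }
  }
})

test_that("sampled sets summarize the GC distribution deterministically", {
  k6 <- make_network("complete", n = 6)
  res <- sampled_set_gc(k6, node_labels(k6), size = 6, samples = 3, seed = 1)
  expect_equal(res$values, rep(1, 3))   # only one possible subset
  expect_equal(res$sem, 0)

  g <- random_net(12, 0.3, seed = 41)
  one <- sampled_set_gc(g, node_labels(g), size = 3, samples = 1, seed = 9)
  direct <- game_centrality_set(g, one$sets[[1]], seed = 9 + 100000)
  expect_equal(one$mean, direct$gc)

  r1 <- sampled_set_gc(g, node_labels(g), size = 3, samples = 4, seed = 2)
  r2 <- sampled_set_gc(g, node_labels(g), size = 3, samples = 4, seed = 2)
  expect_identical(r1$values, r2$values)
  expect_identical(r1$sets, r2$sets)
  expect_error(sampled_set_gc(g, c("n1", "n2"), size = 3, samples = 1),
               "exceeds pool")
})

test_that("gc_table ranks targets with shared ties", {
  st <- make_network("star", leaves = 5)
  tab <- gc_table(st, seed = 1)
  expect_equal(tab$target[1], "n1")
  expect_equal(tab$gc[1], 1.0)
  expect_equal(tab$rank[1], 1L)
  expect_equal(tab$gc[-1], rep(0, 5))
  expect_equal(tab$rank[-1], rep(2L, 5))

  k4 <- make_network("complete", n = 4)
  tab <- gc_table(k4, seed = 1)
  expect_equal(tab$gc, rep(1, 4))
  expect_equal(tab$rank, rep(1L, 4))

  expect_equal(nrow(gc_table(k4, character())), 0)

  # edge targets via a two-column matrix
  tab <- gc_table(k4, cbind(c("n1", "n2"), c("n2", "n3")), seed = 1)
  expect_equal(tab$gc, c(1, 1))
  expect_true(all(grepl("\\+", tab$target)))
})

test_that("hub GC dominates leaf GC on stars for the canonical dilemma", {
  for (k in c(4, 7)) {
    st <- make_network("star", leaves = k)
    hub <- game_centrality_node(st, "n1", seed = 2)$gc
    leaf <- game_centrality_node(st, "n3", seed = 2)$gc
    expect_gte(hub, leaf)
  }
})
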