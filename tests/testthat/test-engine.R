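pd <- game_preset("pd_canonical")

test_that("best-takes-over adopts the closed-neighborhood maximum", {
  # path b - a - c: payoffs set by hand via a crafted state
  net <- network(c("a", "b", "c"), from = c(1, 1), to = c(2, 3))
  # focal a cooperates; neighbor b defects against both -> b gets T from a
  s <- c("C", "D", "C")
  pay <- round_payoffs(net, s, pd)     # a: S+R=3, b: T=6, c: R=3
  expect_equal(unname(pay), c(3, 6, 3))
  expect_equal(update_best_takes_over(1, pay, s, net), "D")

  # a strictly greatest keeps its own strategy
  pay2 <- c(9, 6, 3)
  expect_equal(update_best_takes_over(1, pay2, c("D", "C", "C"), net), "D")

  # exact tie between focal and one neighbor: both outcomes occur
  tie_net <- network(c("a", "b"), from = 1, to = 2)
  picks <- vapply(1:400, function(seed) {
    set.seed(seed)
    update_best_takes_over(1, c(6, 6), c("C", "D"), tie_net)
  }, "")
  expect_true(all(c("C", "D") %in% picks))
  expect_gt(mean(picks == "D"), 0.35)  # ~ Binomial(400, 1/2)
  expect_lt(mean(picks == "D"), 0.65)

  # isolated node keeps its strategy
  iso <- network(c("a", "b"), from = 1, to = 2)
  iso <- network(c("a", "b", "z"), from = 1, to = 2)
  expect_equal(update_best_takes_over(3, c(0, 0, 0), c("C", "C", "D"), iso),
               "D")
})

test_that("Fermi rule follows the pairwise-comparison form", {
  pair <- network(c("a", "b"), from = 1, to = 2)
  # equal payoffs: adoption probability exactly 1/2
  adopt <- vapply(1:2000, function(seed) {
    set.seed(seed)
    update_fermi(1, c(5, 5), c("C", "D"), pair, K = 0.1) == "D"
  }, TRUE)
  expect_gt(mean(adopt), 0.46)
  expect_lt(mean(adopt), 0.54)

  # K = 0.1, payoff deficit 1: adoption probability 1/(1+e^-10)
  p_target <- 1 / (1 + exp(-10))
  expect_equal(p_target, 0.9999546, tolerance = 1e-5)
  adopt <- vapply(1:500, function(seed) {
    set.seed(seed)
    update_fermi(1, c(1, 2), c("C", "D"), pair, K = 0.1) == "D"
  }, TRUE)
  expect_gt(mean(adopt), 0.98)

  # overwhelming deficit: adoption nearly certain even at large K
  set.seed(1)
  expect_equal(update_fermi(1, c(0, 1e6), c("C", "D"), pair, K = 0.1), "D")
})

test_that("proportional rule never imitates downhill and scales uphill", {
  pair <- network(c("a", "b"), from = 1, to = 2)
  # neighbor not better: keep with probability 1, no RNG consumed
  set.seed(1); before <- .Random.seed
  expect_equal(update_proportional(1, c(5, 5), c("C", "D"), pair, pd), "C")
  # maximal payoff gap with k = 1: adoption probability (6-0)/(1*6) = 1
  for (seed in 1:20) {
    set.seed(seed)
    expect_equal(update_proportional(1, c(0, 6), c("C", "D"), pair, pd), "D")
  }
  # identical strategies are absorbing under any draw
  set.seed(3)
  expect_equal(update_proportional(1, c(0, 6), c("D", "D"), pair, pd), "D")
  degen <- payoff_matrix(R = 1, S = 1, T = 1, P = 1)
  set.seed(4)
  expect_error(update_proportional(1, c(0, 6), c("C", "D"), pair, degen),
               "degenerate")
})

test_that("synchronous step matches the enumerated small-graph oracles", {
  # K_5, one defector: defector earns 4T = 24 > every cooperator's 3R + S = 9
  k5 <- make_network("complete", n = 5)
  s1 <- step_game(k5, initial_strategies(k5, "n1"), pd)
  expect_equal(s1, rep("D", 5))

  # star, one defecting leaf: hub earns 4R = 12 > leaf's T = 6, all heal
  st <- make_network("star", leaves = 5)
  s1 <- step_game(st, initial_strategies(st, "n2"), pd)
  expect_equal(s1, rep("C", 6))

  # uniform states are absorbing for every rule and schedule
  for (rule in c("best_takes_over", "fermi", "proportional")) {
    for (sched in c("synchronous", "semi_synchronous")) {
      set.seed(7)
      expect_equal(step_game(k5, rep("C", 5), pd, rule_spec(rule), sched),
                   rep("C", 5))
      set.seed(8)
      expect_equal(step_game(k5, rep("D", 5), pd, rule_spec(rule), sched),
                   rep("D", 5))
    }
  }
})

test_that("run_game records traces and is seed-reproducible", {
  k5 <- make_network("complete", n = 5)
  tr <- run_game(k5, initial_strategies(k5, "n1"), pd, rounds = 5, seed = 1)
  expect_equal(tr$defector_fraction, c(0.2, 1, 1, 1, 1, 1))
  expect_equal(length(tr$defector_fraction), tr$rounds + 1)

  allD <- run_game(k5, rep("D", 5), pd, rounds = 10, seed = 2)
  expect_equal(allD$defector_fraction, rep(1, 11))

  g <- random_net(10, 0.4, seed = 9)
  for (rule in c("best_takes_over", "fermi", "proportional")) {
    a <- run_game(g, initial_strategies(g, "n1"), pd,
                  rule_spec(rule), "semi_synchronous", rounds = 15, seed = 42)
    b <- run_game(g, initial_strategies(g, "n1"), pd,
                  rule_spec(rule), "semi_synchronous", rounds = 15, seed = 42)
    expect_identical(a$defector_fraction, b$defector_fraction)
    expect_identical(a$final_strategies, b$final_strategies)
  }
  expect_true(all(a$defector_fraction >= 0 & a$defector_fraction <= 1))
})

test_that("engine matches the naive reference on random graphs", {
  # smaller version of the full equivalence suite in the acceptance tests
  combos <- expand.grid(rule = c("best_takes_over", "fermi", "proportional"),
                        sched = c("synchronous", "semi_synchronous"),
                        stringsAsFactors = FALSE)
  for (g_seed in 1:10) {
    net <- random_net(n = 5 + g_seed %% 6, p = 0.5, seed = g_seed)
    defs <- paste0("n", 1 + g_seed %% n_nodes(net))
    for (k in seq_len(nrow(combos))) {
      tr <- run_game(net, initial_strategies(net, defs), pd,
                     rule_spec(combos$rule[k]), combos$sched[k],
                     rounds = 12, seed = 1000 + g_seed)
      ref <- ref_run(net, initial_strategies(net, defs), pd,
                     combos$rule[k], combos$sched[k], FALSE, 12,
                     seed = 1000 + g_seed)
      expect_identical(tr$defector_fraction, ref$defector_fraction)
      expect_identical(unname(tr$final_strategies), ref$final_strategies)
    }
  }
  # weighted edges as play probabilities, both schedules
  net <- random_net(8, 0.6, seed = 77)
  net$edges$weight <- round(seq(0.1, 0.9, length.out = n_edges(net)), 2)
  net$adj <- netgame:::build_adjacency(n_nodes(net), net$edges)
  for (sched in c("synchronous", "semi_synchronous")) {
    tr <- run_game(net, initial_strategies(net, "n2"), pd, rule_spec("fermi"),
                   sched, weight_mode = TRUE, rounds = 10, seed = 5)
    ref <- ref_run(net, initial_strategies(net, "n2"), pd, "fermi", sched,
                   TRUE, 10, seed = 5)
    expect_identical(tr$defector_fraction, ref$defector_fraction)
  }
})

test_that("automorphism-equivalent defectors yield identical deterministic traces", {
  nets <- list(make_network("ring_lattice", n = 6),
               make_network("star", leaves = 5),
               make_network("complete", n = 4),
               make_network("grid", rows = 2, cols = 3))
  for (net in nets) {
    orbits <- brute_orbits(net)
    traces <- lapply(seq_len(n_nodes(net)), function(i) {
      t1 <- run_game(net, initial_strategies(net, i), pd, rounds = 20,
                     seed = 1)$defector_fraction
      t2 <- run_game(net, initial_strategies(net, i), pd, rounds = 20,
                     seed = 2)$defector_fraction
      if (identical(t1, t2)) t1 else NULL   # NULL: tie-break stochasticity
    })
    for (orb in orbits) {
      det <- Filter(Negate(is.null), traces[orb])
      if (length(det) > 1) {
        for (k in 2:length(det)) expect_identical(det[[k]], det[[1]])
      }
    }
  }
})

test_that("plugin rules register, run reproducibly, and reject collisions", {
  on.exit(unregister_rule("always_defect"), add = TRUE)
  register_rule("always_defect", function(focal, payoffs, s, net, params) "D")
  expect_error(register_rule("fermi", function(...) "C"), "built-in")
  expect_error(register_rule("always_defect", function(...) "C"),
               "already registered")
  expect_true("always_defect" %in% list_rules())

  k4 <- make_network("complete", n = 4)
  tr <- run_game(k4, initial_strategies(k4), pd, rule_spec("always_defect"),
                 rounds = 1, seed = 1)
  expect_equal(unname(tr$final_strategies), rep("D", 4))

  on.exit(unregister_rule("noisy"), add = TRUE)
  register_rule("noisy", function(focal, payoffs, s, net, params)
    if (runif(1) < 0.5) "C" else "D")
  a <- run_game(k4, initial_strategies(k4, 1), pd, rule_spec("noisy"),
                rounds = 10, seed = 3)
  b <- run_game(k4, initial_strategies(k4, 1), pd, rule_spec("noisy"),
                rounds = 10, seed = 3)
  expect_identical(a$defector_fraction, b$defector_fraction)
  expect_error(rule_spec("no_such_rule"), "unknown update rule")
})
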