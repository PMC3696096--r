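# Independent naive reference simulator.
#
# Re-implements one game round and a full run from scratch with plain
# loops and no caching or absorbing-state shortcuts, following the same
# documented RNG draw order as the engine: edge-firing draws in edge
# order, semi-synchronous participation draws in node order, then each
# participating node's rule draws in node order. Used to cross-check
# engine traces bit-for-bit.

ref_adjacency <- function(net) {
  e <- edge_table(net)
  n <- n_nodes(net)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    nb <- sort(c(e$to[e$from == i], e$from[e$to == i]))
    adj[[i]] <- nb
  }
  adj
}

ref_payoffs <- function(net, s, m, weight_mode) {
  e <- edge_table(net)
  n <- n_nodes(net)
  pay1 <- function(a, b) {
    if (a == "C") { if (b == "C") m$R else m$S } else {
      if (b == "C") m$T else m$P }
  }
  play <- rep(TRUE, nrow(e))
  if (weight_mode && nrow(e)) {
    for (k in seq_len(nrow(e))) play[k] <- runif(1) < min(1, e$weight[k])
  }
  pay <- numeric(n)
  for (i in seq_len(n)) {
    tot <- 0
    for (k in seq_len(nrow(e))) {
      if (!play[k]) next
      if (e$from[k] == i) tot <- tot + pay1(s[i], s[e$to[k]])
      else if (e$to[k] == i) tot <- tot + pay1(s[i], s[e$from[k]])
    }
    pay[i] <- tot
  }
  pay
}

ref_rule <- function(rule, i, pay, s, adj, m, K) {
  nb <- adj[[i]]
  if (!length(nb)) return(s[i])
  if (rule == "best_takes_over") {
    cand <- c(i, nb)
    pc <- pay[cand]
    best <- which(pc == max(pc))
    pick <- if (length(best) == 1) best else best[sample.int(length(best), 1)]
    return(s[cand[pick]])
  }
  j <- nb[sample.int(length(nb), 1)]
  if (rule == "fermi") {
    pr <- 1 / (1 + exp((pay[i] - pay[j]) / K))
    return(if (runif(1) < pr) s[j] else s[i])
  }
  # proportional
  if (pay[j] > pay[i]) {
    denom <- max(length(nb), length(adj[[j]])) * (max(m$T, m$R) - min(m$S, m$P))
    if (runif(1) < (pay[j] - pay[i]) / denom) return(s[j])
  }
  s[i]
}

ref_run <- function(net, initial, m, rule, schedule, weight_mode, rounds,
                    seed, K = 0.1, q = 0.5) {
  set.seed(seed)
  adj <- ref_adjacency(net)
  n <- n_nodes(net)
  s <- initial
  frac <- mean(s == "D")
  for (t in seq_len(rounds)) {
    pay <- ref_payoffs(net, s, m, weight_mode)
    part <- if (schedule == "semi_synchronous") runif(n) < q else rep(TRUE, n)
    new_s <- s
    for (i in seq_len(n)) {
      if (part[i]) new_s[i] <- ref_rule(rule, i, pay, s, adj, m, K)
    }
    s <- new_s
    frac <- c(frac, mean(s == "D"))
  }
  list(defector_fraction = frac, final_strategies = s)
}
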