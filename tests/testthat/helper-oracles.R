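# Brute-force oracles used across the suite.

# Exhaustive concordant/discordant pair counter (double loop).
brute_gamma <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      if (dx == 0 || dy == 0) next
      if (sign(dx) == sign(dy)) C <- C + 1L else D <- D + 1L
    }
  }
  list(C = C, D = D, gamma = (C - D) / (C + D))
}

# All permutations of 1..n as a matrix (one per row).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    shifted <- sub + (sub >= k)
    out <- rbind(out, cbind(rep(k, nrow(sub)), shifted))
  }
  out
}

# Automorphism orbits of a small network by brute-force enumeration.
brute_orbits <- function(net) {
  n <- n_nodes(net)
  A <- matrix(0L, n, n)
  e <- edge_table(net)
  A[cbind(e$from, e$to)] <- 1L
  A[cbind(e$to, e$from)] <- 1L
  perms <- all_perms(n)
  auto <- perms[apply(perms, 1, function(p) all(A[p, p] == A)), , drop = FALSE]
  # union-find over node images
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(auto))) {
    for (i in seq_len(n)) {
      a <- find(i); b <- find(auto[r, i])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  unname(split(seq_len(n), roots))
}

# Small random Erdos-Renyi fixture.
random_net <- function(n, p, seed) make_network("erdos_renyi", n = n, p = p,
                                                seed = seed)
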