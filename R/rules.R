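# Registry for user-supplied ("plugin") strategy update rules.
.rules <- new.env(parent = emptyenv())
.builtin_rules <- c("best_takes_over", "fermi", "proportional")

#' Strategy update rule specification
#'
#' Bundles the rule name with its tunables: `K`, the Fermi noise
#' (selection temperature; smaller K means more deterministic
#' imitation), and `q`, the per-node participation probability of the
#' semi-synchronous schedule. Both default values are package choices
#' surfaced here and in every run manifest, never hard-coded into
#' results.
#'
#' @param name `"best_takes_over"`, `"fermi"`, `"proportional"`, or a
#'   rule registered with [register_rule()] (optionally written
#'   `"plugin:<name>"`).
#' @param K Fermi noise, > 0.
#' @param q semi-synchronous update probability, in (0, 1].
#' @param params list of extra parameters passed to plugin rules.
#' @return object of class `rule_spec`.
#' @export
rule_spec <- function(name = "best_takes_over", K = 0.1, q = 0.5,
                      params = list()) {
  stopifnot(is.character(name), length(name) == 1)
  if (!is.numeric(K) || K <= 0) stop("K must be > 0")
  if (!is.numeric(q) || q <= 0 || q > 1) stop("q must be in (0, 1]")
  key <- sub("^plugin:", "", name)
  if (!(key %in% .builtin_rules) && !exists(key, envir = .rules))
    stop("unknown update rule: ", name)
  structure(list(name = key, K = K, q = q, params = params),
            class = "rule_spec")
}

#' Register a plugin strategy update rule
#'
#' A plugin rule is a function `(focal, payoffs, strategies, net,
#' params)` returning `"C"` or `"D"` for the focal node; it may use the
#' current RNG stream (seeded from the run seed, so registered rules
#' stay reproducible). Built-in names and already-registered names are
#' rejected.
#'
#' @param name rule name (without the `plugin:` prefix).
#' @param fn the rule function.
#' @export
register_rule <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1, is.function(fn))
  if (name %in% .builtin_rules)
    stop("'", name, "' is a built-in rule name")
  if (exists(name, envir = .rules))
    stop("rule '", name, "' is already registered")
  assign(name, fn, envir = .rules)
  invisible(NULL)
}

#' @rdname register_rule
#' @export
list_rules <- function() c(.builtin_rules, ls(.rules))

#' @rdname register_rule
#' @export
unregister_rule <- function(name) {
  if (exists(name, envir = .rules)) rm(list = name, envir = .rules)
  invisible(NULL)
}

#' Best-takes-over update for one node
#'
#' The focal node adopts the strategy of the maximal-payoff member of
#' its closed neighborhood (itself plus its neighbors); ties among
#' maximal members are broken uniformly at random. An isolated node
#' keeps its strategy. This is the only stochasticity of the rule, so
#' tie-free runs are fully deterministic.
#'
#' @param focal node index.
#' @param payoffs per-node payoff vector for the current round.
#' @param s current strategy vector.
#' @param net a [network()] object.
#' @return `"C"` or `"D"`.
#' @export
update_best_takes_over <- function(focal, payoffs, s, net) {
  nbrs <- net$adj[[focal]]
  if (!length(nbrs)) return(s[focal])
  cand <- c(focal, nbrs)
  pc <- payoffs[cand]
  best <- which(pc == max(pc))
  pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  s[cand[pick]]
}

#' Fermi (pairwise-comparison) update for one node
#'
#' Picks one neighbor j uniformly at random and adopts its strategy
#' with probability `1 / (1 + exp((pi_focal - pi_j) / K))`: imitation
#' of better-scoring neighbors is likely, of worse-scoring ones
#' unlikely, with noise scale `K`.
#'
#' @inheritParams update_best_takes_over
#' @param K noise (temperature), > 0.
#' @export
update_fermi <- function(focal, payoffs, s, net, K = 0.1) {
  nbrs <- net$adj[[focal]]
  if (!length(nbrs)) return(s[focal])
  j <- nbrs[sample.int(length(nbrs), 1L)]
  pr <- 1 / (1 + exp((payoffs[focal] - payoffs[j]) / K))
  if (stats::runif(1) < pr) s[j] else s[focal]
}

#' Proportional (replicator-type) update for one node
#'
#' Picks one neighbor j uniformly; if j scored higher, adopts its
#' strategy with probability `(pi_j - pi_focal) / (max(k_focal, k_j) *
#' (max(T, R) - min(S, P)))`, the replicator normalization by the
#' largest possible payoff difference. Never imitates downhill.
#'
#' @inheritParams update_best_takes_over
#' @param m the [payoff_matrix()] in play (sets the normalization).
#' @export
update_proportional <- function(focal, payoffs, s, net, m) {
  nbrs <- net$adj[[focal]]
  if (!length(nbrs)) return(s[focal])
  j <- nbrs[sample.int(length(nbrs), 1L)]
  if (payoffs[j] > payoffs[focal]) {
    rng <- max(m$T, m$R) - min(m$S, m$P)
    if (rng <= 0) stop("degenerate payoff matrix: max(T, R) = min(S, P)")
    kmax <- max(length(nbrs), length(net$adj[[j]]))
    pr <- (payoffs[j] - payoffs[focal]) / (kmax * rng)
    if (stats::runif(1) < pr) return(s[j])
  }
  s[focal]
}

# Dispatch one rule application; consumes RNG draws in a fixed order so
# that independently written simulators can reproduce traces bit-for-bit.
apply_rule <- function(focal, payoffs, s, net, m, spec) {
  switch(spec$name,
    best_takes_over = update_best_takes_over(focal, payoffs, s, net),
    fermi = update_fermi(focal, payoffs, s, net, spec$K),
    proportional = update_proportional(focal, payoffs, s, net, m),
    {
      fn <- get(spec$name, envir = .rules)
      fn(focal, payoffs, s, net, spec$params)
    })
}
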