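#' One synchronized game round: play then update
#'
#' Payoffs are computed once from the current strategies; every update
#' then sees those pre-step payoffs and strategies. Under the
#' synchronous schedule all nodes apply the rule simultaneously; under
#' the semi-synchronous schedule each node participates this round with
#' independent probability `spec$q`, non-participants keeping their
#' strategy.
#'
#' RNG draw order per step (the contract reference simulators must
#' follow to reproduce traces): (1) with `weight_mode`, one
#' `runif(n_edges)` block for edge firing, in edge-table order; (2) for
#' the semi-synchronous schedule, one `runif(n_nodes)` participation
#' block; (3) each participating node's rule draws, in node order.
#'
#' @param net a [network()] object.
#' @param s current strategy vector (`"C"`/`"D"`, node order).
#' @param m a [payoff_matrix()].
#' @param spec a [rule_spec()].
#' @param schedule `"synchronous"` or `"semi_synchronous"`.
#' @param weight_mode read edge weights as play probabilities.
#' @return the post-step strategy vector.
#' @export
step_game <- function(net, s, m, spec = rule_spec(),
                      schedule = c("synchronous", "semi_synchronous"),
                      weight_mode = FALSE) {
  schedule <- match.arg(schedule)
  n <- n_nodes(net)
  payoffs <- round_payoffs(net, s, m, weight_mode)
  part <- if (schedule == "semi_synchronous") stats::runif(n) < spec$q
          else rep(TRUE, n)
  new_s <- s
  for (i in seq_len(n)) {
    if (part[i]) new_s[i] <- apply_rule(i, payoffs, s, net, m, spec)
  }
  new_s
}

#' Run a repeated spatial game
#'
#' Iterates [step_game()] from an initial strategy assignment, recording
#' the defector fraction each round (round 0 is the initial state).
#' Either a fixed number of rounds is played, or rounds continue until
#' the trailing-window drift criterion of a [convergence_spec()] is met
#' (or its `max_rounds` cap is hit, in which case the trace is flagged
#' non-converged rather than raising an error). Identical seeds give
#' identical traces.
#'
#' Uniform states (all-C, all-D) are absorbing under every built-in
#' rule, so once one is reached the remaining rounds are filled without
#' further simulation.
#'
#' @inheritParams step_game
#' @param initial initial strategy vector (see [initial_strategies()]).
#' @param rounds fixed round count; give either this or `convergence`.
#' @param convergence a [convergence_spec()].
#' @param seed integer seed; all stochastic choices of the run flow
#'   from it.
#' @return object of class `game_trace`: list with `defector_fraction`
#'   (length `rounds + 1`), `final_strategies`, `rounds`, `seed`,
#'   `converged` (`NA` for fixed-round runs).
#' @export
#' @examples
#' net <- make_network("complete", n = 5)
#' tr <- run_game(net, initial_strategies(net, "n1"), game_preset("pd_canonical"),
#'                rounds = 5, seed = 1)
#' tr$defector_fraction  # 0.2 then fixation at 1
run_game <- function(net, initial, m, spec = rule_spec(),
                     schedule = c("synchronous", "semi_synchronous"),
                     weight_mode = FALSE, rounds = NULL, convergence = NULL,
                     seed = 1L) {
  schedule <- match.arg(schedule)
  if (is.null(rounds) == is.null(convergence))
    stop("give exactly one of 'rounds' or 'convergence'")
  if (length(initial) != n_nodes(net))
    stop("initial strategies do not match network size")
  with_seed(seed, {
    s <- initial
    frac <- mean(s == "D")
    conv <- NA
    plugin_rule <- !(spec$name %in% .builtin_rules)
    if (!is.null(rounds)) {
      t <- 0L
      while (t < rounds) {
        if (!plugin_rule && uniform_state(s)) {
          frac <- c(frac, rep(frac[length(frac)], rounds - t))
          t <- rounds
          break
        }
        s <- step_game(net, s, m, spec, schedule, weight_mode)
        frac <- c(frac, mean(s == "D"))
        t <- t + 1L
      }
    } else {
      cs <- convergence
      t <- 0L
      repeat {
        if (drift_converged(frac, cs)) { conv <- TRUE; break }
        if (t >= cs$max_rounds) { conv <- FALSE; break }
        if (!plugin_rule && uniform_state(s)) {
          # absorbing: append constant fractions until drift settles
          f <- frac[length(frac)]
          while (t < cs$max_rounds && !drift_converged(frac, cs)) {
            frac <- c(frac, f)
            t <- t + 1L
          }
          next
        }
        s <- step_game(net, s, m, spec, schedule, weight_mode)
        frac <- c(frac, mean(s == "D"))
        t <- t + 1L
      }
      rounds <- t
    }
    structure(list(defector_fraction = frac,
                   final_strategies = stats::setNames(s, net$labels),
                   rounds = rounds, seed = seed, converged = conv),
              class = "game_trace")
  })
}

uniform_state <- function(s) {
  all(s == "C") || all(s == "D")
}

#' @export
print.game_trace <- function(x, ...) {
  cat(sprintf("<game_trace> %d rounds, final defector fraction %.3f%s\n",
              x$rounds, x$defector_fraction[length(x$defector_fraction)],
              if (isFALSE(x$converged)) " (drift NOT converged)" else ""))
  invisible(x)
}

#' Write a trace as TSV
#'
#' Two columns: `round` (0-based) and `defector_fraction`.
#'
#' @param trace a `game_trace`.
#' @param file output path.
#' @export
write_trace <- function(trace, file) {
  utils::write.table(
    data.frame(round = seq_along(trace$defector_fraction) - 1L,
               defector_fraction = trace$defector_fraction),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
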