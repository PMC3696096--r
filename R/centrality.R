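#' Stopping rules for game-centrality estimation
#'
#' Two thresholds control the estimate. The drift threshold stops a
#' single replicate: rounds continue until the mean defector fraction of
#' the last `window` rounds differs from the mean of the previous
#' `window` rounds by less than `drift_threshold`. The fluctuation
#' threshold stops replicate batching: replicates are added until the
#' standard error of the per-replicate windowed means falls below
#' `sem_threshold`. Defaults follow the published protocol: a 50-round
#' window and 0.01 for both thresholds.
#'
#' @param window trailing-window length in rounds (default 50).
#' @param drift_threshold per-replicate drift stopping threshold.
#' @param sem_threshold across-replicate standard-error threshold.
#' @param min_replicates,max_replicates replicate batching bounds.
#' @param max_rounds per-replicate safety cap; hitting it flags the
#'   estimate non-converged instead of erroring (lattice-like dynamics
#'   may never settle).
#' @param batch replicates added between standard-error checks.
#' @return object of class `convergence_spec`.
#' @export
convergence_spec <- function(window = 50L, drift_threshold = 0.01,
                             sem_threshold = 0.01, min_replicates = 10L,
                             max_replicates = 10000L, max_rounds = 10000L,
                             batch = 10L) {
  stopifnot(window >= 1, drift_threshold > 0, sem_threshold > 0,
            min_replicates >= 1, min_replicates <= max_replicates,
            max_rounds >= 1, batch >= 1)
  structure(list(window = as.integer(window),
                 drift_threshold = drift_threshold,
                 sem_threshold = sem_threshold,
                 min_replicates = as.integer(min_replicates),
                 max_replicates = as.integer(max_replicates),
                 max_rounds = as.integer(max_rounds),
                 batch = as.integer(batch)),
            class = "convergence_spec")
}

#' Trailing-window drift test
#'
#' `TRUE` iff the absolute difference between the mean of the last
#' `window` values and the mean of the `window` values before them is
#' below the drift threshold. With fewer than `2 * window` values the
#' drift cannot be assessed and the result is `FALSE`.
#'
#' @param fracs per-round mean defector fractions.
#' @param spec a [convergence_spec()].
#' @return logical flag.
#' @export
drift_converged <- function(fracs, spec = convergence_spec()) {
  w <- spec$window
  n <- length(fracs)
  if (n < 2L * w) return(FALSE)
  last <- mean(fracs[(n - w + 1L):n])
  prev <- mean(fracs[(n - 2L * w + 1L):(n - w)])
  abs(last - prev) < spec$drift_threshold
}

# One replicate: run to drift convergence (or the cap) and return the
# windowed mean of its own trace.
gc_replicate <- function(net, defectors, m, spec, schedule, weight_mode,
                         cs, seed) {
  tr <- run_game(net, initial_strategies(net, defectors), m, spec,
                 schedule, weight_mode, convergence = cs, seed = seed)
  fr <- tr$defector_fraction
  w <- min(cs$window, length(fr))
  list(gc = mean(fr[(length(fr) - w + 1L):length(fr)]),
       rounds = tr$rounds, converged = isTRUE(tr$converged))
}

gc_estimate <- function(target, vals, rounds, drift_ok, cs) {
  reps <- length(vals)
  sem <- if (reps >= 2L) stats::sd(vals) / sqrt(reps) else NA_real_
  structure(list(target = target, gc = mean(vals), sem = sem,
                 replicates = reps, rounds = rounds, values = vals,
                 converged = drift_ok && !is.na(sem) && sem < cs$sem_threshold),
            class = "gc_estimate")
}

#' Game centrality of a node, linked pair, or node set
#'
#' Game centrality measures a node's power to break cooperation: start
#' the network fully cooperative except for the target defector(s), run
#' the repeated game to drift convergence, and take the defector
#' fraction averaged over the final window. Replicates (replicate `r`
#' is seeded `seed + r`) are added in batches until the standard error
#' of the per-replicate values falls below the fluctuation threshold;
#' the estimate is their mean.
#'
#' `game_centrality_node()` seeds a single defector,
#' `game_centrality_edge()` a linked pair (the endpoints must be
#' adjacent), `game_centrality_set()` an arbitrary nonempty node set.
#'
#' @param net a [network()] object.
#' @param node,u,v,nodes the initial defector(s), as labels or indices.
#' @param m a [payoff_matrix()] (default the canonical prisoner's
#'   dilemma R=3, S=0, T=6, P=1).
#' @param spec a [rule_spec()] (default best-takes-over).
#' @param schedule `"synchronous"` (default) or `"semi_synchronous"`.
#' @param weight_mode read edge weights as play probabilities.
#' @param cs a [convergence_spec()].
#' @param seed root seed; replicate `r` uses `seed + r`.
#' @return object of class `gc_estimate`: `target`, `gc` (mean over
#'   replicates, in [0, 1]), `sem`, `replicates`, `rounds`
#'   (per-replicate counts), `values`, `converged`.
#' @export
#' @examples
#' net <- make_network("star", leaves = 5)
#' game_centrality_node(net, "n1")$gc  # hub defection fixates: 1
#' game_centrality_node(net, "n2")$gc  # leaf defection heals: 0
game_centrality_set <- function(net, nodes, m = game_preset("pd_canonical"),
                                spec = rule_spec(),
                                schedule = "synchronous",
                                weight_mode = FALSE,
                                cs = convergence_spec(), seed = 1L) {
  if (!length(nodes)) stop("defector set must be nonempty")
  idx <- node_index(net, nodes)
  target <- paste(net$labels[idx], collapse = "+")
  vals <- numeric(); rounds <- integer(); drift_ok <- TRUE
  reps <- 0L
  repeat {
    take <- if (reps == 0L) cs$min_replicates
            else min(cs$batch, cs$max_replicates - reps)
    for (r in seq_len(take)) {
      one <- gc_replicate(net, idx, m, spec, schedule, weight_mode, cs,
                          seed = seed + reps + r)
      vals <- c(vals, one$gc); rounds <- c(rounds, one$rounds)
      drift_ok <- drift_ok && one$converged
    }
    reps <- reps + take
    sem <- if (reps >= 2L) stats::sd(vals) / sqrt(reps) else Inf
    if (sem < cs$sem_threshold || reps >= cs$max_replicates) break
  }
  gc_estimate(target, vals, rounds, drift_ok, cs)
}

#' @rdname game_centrality_set
#' @export
game_centrality_node <- function(net, node, ...) {
  idx <- node_index(net, node)
  if (length(idx) != 1L) stop("give a single node")
  game_centrality_set(net, idx, ...)
}

#' @rdname game_centrality_set
#' @export
game_centrality_edge <- function(net, u, v, ...) {
  if (!has_edge(net, u, v))
    stop("edge game centrality is defined for linked pairs; '",
         u, "' and '", v, "' are not adjacent")
  game_centrality_set(net, c(node_index(net, u), node_index(net, v)), ...)
}

#' @export
print.gc_estimate <- function(x, ...) {
  cat(sprintf("<gc_estimate> %s: GC = %.4f (SEM %.2g, %d replicates%s)\n",
              x$target, x$gc, x$sem, x$replicates,
              if (!x$converged) ", NOT converged" else ""))
  invisible(x)
}

#' Game centrality of randomly sampled node sets
#'
#' Draws `samples` uniform subsets of `size` nodes (without replacement
#' within a subset) from `pool`, computes the set game centrality of
#' each, and summarizes the distribution. The raw per-sample values are
#' returned for distribution comparisons such as [chi_square_gc()].
#'
#' Seeding: the subset sequence is drawn from `seed`; sample `k`'s
#' replicates use root seed `seed + k * 100000`, keeping replicate
#' streams disjoint across samples.
#'
#' @inheritParams game_centrality_set
#' @param pool candidate node labels or indices.
#' @param size subset size, at most `length(pool)`.
#' @param samples number of subsets to draw.
#' @return list with `mean`, `sem`, `values` (per-sample GC), `sets`
#'   (list of sampled label vectors), `n_converged`.
#' @export
sampled_set_gc <- function(net, pool, size, samples,
                           m = game_preset("pd_canonical"),
                           spec = rule_spec(), schedule = "synchronous",
                           weight_mode = FALSE, cs = convergence_spec(),
                           seed = 1L) {
  pool <- node_index(net, pool)
  if (size > length(pool)) stop("size exceeds pool size")
  if (samples < 1) stop("need at least one sample")
  sets <- with_seed(seed, lapply(seq_len(samples), function(k)
    sort(pool[sample.int(length(pool), size)])))
  vals <- numeric(samples); n_conv <- 0L
  out_sets <- vector("list", samples)
  for (k in seq_len(samples)) {
    est <- game_centrality_set(net, sets[[k]], m, spec, schedule,
                               weight_mode, cs, seed = seed + k * 100000)
    vals[k] <- est$gc
    n_conv <- n_conv + est$converged
    out_sets[[k]] <- net$labels[sets[[k]]]
  }
  ms <- mean_sem(vals)
  list(mean = ms$mean, sem = ms$sem, values = vals, sets = out_sets,
       n_converged = n_conv)
}

#' Ranked game-centrality table
#'
#' Computes the game centrality of every target and returns a table
#' sorted by decreasing GC, equal values sharing a rank.
#'
#' @inheritParams game_centrality_set
#' @param targets `NULL` for all nodes, a vector of node labels/indices,
#'   or a two-column matrix/data.frame of edge endpoints.
#' @return data.frame with columns `target`, `gc`, `sem`, `replicates`,
#'   `mean_rounds`, `converged`, `rank`.
#' @export
gc_table <- function(net, targets = NULL, m = game_preset("pd_canonical"),
                     spec = rule_spec(), schedule = "synchronous",
                     weight_mode = FALSE, cs = convergence_spec(),
                     seed = 1L) {
  ests <- if (is.null(targets)) {
    lapply(seq_len(n_nodes(net)), function(i)
      game_centrality_node(net, i, m = m, spec = spec, schedule = schedule,
                           weight_mode = weight_mode, cs = cs, seed = seed))
  } else if (is.matrix(targets) || is.data.frame(targets)) {
    lapply(seq_len(nrow(targets)), function(r)
      game_centrality_edge(net, targets[r, 1][[1]], targets[r, 2][[1]],
                           m = m, spec = spec, schedule = schedule,
                           weight_mode = weight_mode, cs = cs, seed = seed))
  } else {
    lapply(targets, function(i)
      game_centrality_node(net, i, m = m, spec = spec, schedule = schedule,
                           weight_mode = weight_mode, cs = cs, seed = seed))
  }
  if (!length(ests)) {
    return(data.frame(target = character(), gc = numeric(), sem = numeric(),
                      replicates = integer(), mean_rounds = numeric(),
                      converged = logical(), rank = integer()))
  }
  tab <- data.frame(
    target = vapply(ests, `[[`, "", "target"),
    gc = vapply(ests, `[[`, 0, "gc"),
    sem = vapply(ests, `[[`, 0, "sem"),
    replicates = vapply(ests, `[[`, 0L, "replicates"),
    mean_rounds = vapply(ests, function(e) mean(e$rounds), 0),
    converged = vapply(ests, `[[`, TRUE, "converged"))
  tab <- tab[order(-tab$gc, tab$target), , drop = FALSE]
  tab$rank <- rank(-tab$gc, ties.method = "min")
  rownames(tab) <- NULL
  tab
}
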