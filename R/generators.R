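# Run code with a locally-seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic network
#'
#' Deterministic (for a fixed `seed`) graph generators used by the test
#' suite and demos. Nodes are labeled `n1` ... `nN`.
#'
#' @param kind one of `"complete"`, `"star"`, `"ring_lattice"`, `"grid"`,
#'   `"erdos_renyi"`, `"barabasi_albert"`.
#' @param n node count (`"star"`: use `leaves`; `"grid"`: use `rows`/`cols`).
#' @param leaves number of leaves for `"star"` (hub is node `n1`).
#' @param k for `"ring_lattice"`: each node is linked to its `k` nearest
#'   neighbors on each side (so degree `2k`).
#' @param rows,cols grid dimensions for `"grid"`.
#' @param p edge probability for `"erdos_renyi"`.
#' @param m edges added per step for `"barabasi_albert"`.
#' @param seed integer seed for the random generators; the caller's RNG
#'   stream is left untouched.
#' @return a [network()] object.
#' @export
#' @examples
#' make_network("complete", n = 5)          # K_5: 10 edges
#' make_network("star", leaves = 5)         # hub n1, degree 5
make_network <- function(kind = c("complete", "star", "ring_lattice", "grid",
                                  "erdos_renyi", "barabasi_albert"),
                         n = NULL, leaves = NULL, k = 1L,
                         rows = NULL, cols = NULL, p = NULL, m = 1L,
                         seed = NULL) {
  kind <- match.arg(kind)
  need <- function(x, what) {
    if (is.null(x) || !is.finite(x) || x < 1) stop("invalid ", what, " for kind '", kind, "'")
    as.integer(x)
  }
  g <- switch(kind,
    complete = igraph::make_full_graph(need(n, "n")),
    star = igraph::make_star(need(leaves, "leaves") + 1L, mode = "undirected",
                             center = 1L),
    ring_lattice = {
      nn <- need(n, "n")
      if (nn < 3L) stop("ring_lattice needs n >= 3")
      igraph::make_ring(nn) |>
        (\(gg) if (k > 1L) igraph::connect(gg, order = as.integer(k)) else gg)()
    },
    grid = igraph::make_lattice(c(need(rows, "rows"), need(cols, "cols"))),
    erdos_renyi = {
      if (is.null(p) || p < 0 || p > 1) stop("invalid p for erdos_renyi")
      with_seed(seed, igraph::sample_gnp(need(n, "n"), p))
    },
    barabasi_albert = with_seed(seed,
      igraph::sample_pa(need(n, "n"), m = as.integer(m), directed = FALSE))
  )
  g <- igraph::simplify(g)
  labs <- paste0("n", seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  network(labs, from = el[, 1], to = el[, 2])
}

#' The Zachary karate club network
#'
#' The 34-node, 78-edge social network of a university karate club
#' (Zachary 1977), in its standard numbering (node 1 the instructor,
#' node 34 the club president). Taken from igraph's built-in copy,
#' unweighted; node labels are `"1"` ... `"34"`.
#'
#' @return a [network()] object.
#' @export
karate_network <- function() {
  g <- igraph::make_graph("Zachary")
  el <- igraph::as_edgelist(g, names = FALSE)
  network(as.character(seq_len(igraph::vcount(g))),
          from = el[, 1], to = el[, 2])
}
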