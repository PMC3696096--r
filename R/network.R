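#' Construct a game-arena network
#'
#' A `netgame_network` is an undirected, weighted graph with stable,
#' ordered node labels. It is the arena on which repeated spatial games
#' are played. Invariants enforced by the constructor: no self-loops, no
#' duplicate edges, strictly positive weights, every edge endpoint a
#' declared node.
#'
#' @param labels character vector of unique node labels, in node order.
#' @param from,to edge endpoints; either integer node indices or node labels.
#' @param weight numeric edge weights (recycled); default 1 for every edge.
#' @param names optional per-node display names (same length as `labels`).
#' @param collapse how to treat duplicate/reciprocal edge entries:
#'   `"error"` (default) rejects them, `"first"` keeps the first weight
#'   seen (the Pajek reader's convention).
#' @param drop_loops if `TRUE`, self-loops are dropped with a warning
#'   instead of raising an error.
#'
#' @return an object of class `netgame_network`: a list with elements
#'   `labels`, `names`, `edges` (data.frame `from`, `to`, `weight` with
#'   integer indices, `from < to`) and a precomputed adjacency list `adj`.
#' @export
#' @examples
#' net <- network(c("a", "b", "c"), from = c("a", "b"), to = c("b", "c"),
#'                weight = c(0.5, 2))
#' n_edges(net)
network <- function(labels, from = integer(), to = integer(),
                    weight = 1, names = NULL,
                    collapse = c("error", "first"), drop_loops = FALSE) {
  collapse <- match.arg(collapse)
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("duplicate node labels")
  if (length(from) != length(to)) stop("'from' and 'to' lengths differ")
  if (is.character(from)) from <- match(from, labels)
  if (is.character(to)) to <- match(to, labels)
  from <- as.integer(from); to <- as.integer(to)
  weight <- rep_len(as.numeric(weight), length(from))
  n <- length(labels)
  if (length(from)) {
    if (anyNA(from) || anyNA(to) || any(from < 1L) || any(to < 1L) ||
        any(from > n) || any(to > n))
      stop("edge endpoint is not a declared node")
    if (anyNA(weight) || any(!is.finite(weight)) || any(weight <= 0))
      stop("edge weights must be finite and strictly positive")
    loops <- from == to
    if (any(loops)) {
      if (!drop_loops) stop("self-loops are not allowed")
      warning(sprintf("dropped %d self-loop(s)", sum(loops)))
      from <- from[!loops]; to <- to[!loops]; weight <- weight[!loops]
    }
    lo <- pmin(from, to); hi <- pmax(from, to)
    key <- paste(lo, hi)
    if (anyDuplicated(key)) {
      if (collapse == "error") stop("duplicate edges are not allowed")
      keep <- !duplicated(key)
      lo <- lo[keep]; hi <- hi[keep]; weight <- weight[keep]
    }
    ord <- order(lo, hi)
    edges <- data.frame(from = lo[ord], to = hi[ord], weight = weight[ord])
  } else {
    edges <- data.frame(from = integer(), to = integer(), weight = numeric())
  }
  if (!is.null(names)) {
    names <- as.character(names)
    if (length(names) != n) stop("'names' must match 'labels' in length")
  }
  out <- structure(
    list(labels = labels, names = names, edges = edges,
         adj = build_adjacency(n, edges)),
    class = "netgame_network")
  out
}

build_adjacency <- function(n, edges) {
  adj <- rep(list(integer()), n)
  if (nrow(edges)) {
    ends <- c(edges$from, edges$to)
    nbrs <- c(edges$to, edges$from)
    ord <- order(ends, nbrs)
    adj <- unname(split(nbrs[ord], factor(ends[ord], levels = seq_len(n))))
  }
  adj
}

#' @rdname network
#' @param net a `netgame_network`.
#' @export
n_nodes <- function(net) length(net$labels)

#' @rdname network
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname network
#' @export
node_labels <- function(net) net$labels

#' Edge table of a network
#'
#' @param net a `netgame_network`.
#' @param labels if `TRUE`, return endpoint labels instead of indices.
#' @return data.frame with columns `from`, `to`, `weight`.
#' @export
edge_table <- function(net, labels = FALSE) {
  e <- net$edges
  if (labels && nrow(e)) {
    e$from <- net$labels[e$from]
    e$to <- net$labels[e$to]
  }
  e
}

#' Node degrees of a network
#' @param net a `netgame_network`.
#' @return integer vector named by node label.
#' @export
node_degree <- function(net) {
  d <- lengths(net$adj)
  names(d) <- net$labels
  d
}

# Resolve labels or indices to validated integer node indices.
node_index <- function(net, nodes) {
  if (is.character(nodes)) {
    idx <- match(nodes, net$labels)
    if (anyNA(idx))
      stop("unknown node(s): ", paste(nodes[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(nodes)
    if (anyNA(idx) || any(idx < 1L) || any(idx > n_nodes(net)))
      stop("node index out of range")
  }
  idx
}

has_edge <- function(net, u, v) {
  u <- node_index(net, u); v <- node_index(net, v)
  v %in% net$adj[[u]]
}

#' Convert to/from igraph
#'
#' @param net a `netgame_network`.
#' @return `as_igraph()` returns an [igraph::graph] with a `weight` edge
#'   attribute; `from_igraph()` builds a `netgame_network` from any
#'   undirected igraph object (missing weights default to 1).
#' @param g an igraph object.
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(n = n_nodes(net), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$labels)
  if (n_edges(net)) {
    g <- igraph::add_edges(g, rbind(net$edges$from, net$edges$to))
    g <- igraph::set_edge_attr(g, "weight", value = net$edges$weight)
  }
  g
}

#' @rdname as_igraph
#' @export
from_igraph <- function(g) {
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  labs <- igraph::vertex_attr(g, "name")
  if (is.null(labs)) labs <- paste0("n", seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- igraph::edge_attr(g, "weight")
  if (is.null(w)) w <- rep(1, nrow(el))
  network(labs, from = el[, 1], to = el[, 2], weight = w,
          collapse = "first", drop_loops = TRUE)
}

#' @export
print.netgame_network <- function(x, ...) {
  cat(sprintf("<netgame_network> %d nodes, %d edges\n",
              n_nodes(x), n_edges(x)))
  w <- x$edges$weight
  if (length(w) && !all(w == 1))
    cat(sprintf("  weighted: range [%g, %g]\n", min(w), max(w)))
  if (n_nodes(x))
    cat("  nodes: ", paste(utils::head(x$labels, 6), collapse = ", "),
        if (n_nodes(x) > 6) ", ..." else "", "\n", sep = "")
  invisible(x)
}
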