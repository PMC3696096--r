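#' Payoff matrix of a symmetric 2-strategy game
#'
#' The four payoffs of a symmetric two-strategy normal-form game in the
#' social-dilemma convention: `R` reward (C vs C), `S` sucker (C vs D),
#' `T` temptation (D vs C), `P` punishment (D vs D). With `pd = TRUE`
#' the canonical prisoner's-dilemma ordering `T > R > P > S` is checked
#' (advisory: a violation warns, it does not error, so free-form games
#' can reuse the flag).
#'
#' @param R,S,T,P finite numeric payoffs.
#' @param pd flag the matrix as a prisoner's dilemma and check ordering.
#' @return object of class `payoff_matrix`.
#' @export
#' @examples
#' pd <- payoff_matrix(R = 3, S = 0, T = 6, P = 1, pd = TRUE)
#' pair_payoff(pd, "D", "C")  # temptation: 6
payoff_matrix <- function(R, S, T, P, pd = FALSE) {
  v <- c(R = R, S = S, T = T, P = P)
  if (!all(is.finite(v))) stop("payoff entries must be finite")
  if (pd && !(T > R && R > P && P > S))
    warning("payoffs do not satisfy the prisoner's dilemma ordering T > R > P > S")
  structure(as.list(v), class = "payoff_matrix", pd = pd)
}

#' Named game presets
#'
#' `"pd_canonical"`: R=3, S=0, T=6, P=1 (maximal temptation, most
#' stringent test of cooperation). `"pd_strike"`: R=3, S=0, T=3.1, P=1
#' (the milder dilemma used for the strike sociogram). `"weak_pd"`:
#' R=3, S=0, T=6, P=0. `"hawk_dove"`: R=3, S=1, T=5, P=0.
#'
#' @param name preset name.
#' @return a [payoff_matrix()].
#' @export
game_preset <- function(name = c("pd_canonical", "pd_strike", "weak_pd",
                                 "hawk_dove")) {
  switch(match.arg(name),
    pd_canonical = payoff_matrix(R = 3, S = 0, T = 6, P = 1, pd = TRUE),
    pd_strike = payoff_matrix(R = 3, S = 0, T = 3.1, P = 1, pd = TRUE),
    weak_pd = payoff_matrix(R = 3, S = 0, T = 6, P = 0),
    hawk_dove = payoff_matrix(R = 3, S = 1, T = 5, P = 0))
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("<payoff_matrix> R=%g S=%g T=%g P=%g%s\n",
              x$R, x$S, x$T, x$P,
              if (isTRUE(attr(x, "pd"))) " (prisoner's dilemma)" else ""))
  invisible(x)
}

#' Payoff of one player in a single pairwise game
#'
#' @param m a [payoff_matrix()].
#' @param own,other strategies, `"C"` or `"D"`.
#' @return the focal player's payoff: (C,C) -> R, (C,D) -> S,
#'   (D,C) -> T, (D,D) -> P.
#' @export
pair_payoff <- function(m, own, other) {
  stopifnot(own %in% c("C", "D"), other %in% c("C", "D"))
  if (own == "C") { if (other == "C") m$R else m$S }
  else { if (other == "C") m$T else m$P }
}

#' Initial strategy assignment
#'
#' All nodes cooperate except the given defector set.
#'
#' @param net a [network()] object.
#' @param defectors node labels or indices defecting at round 0; may be
#'   empty.
#' @return character vector of `"C"`/`"D"`, one entry per node, in node
#'   order.
#' @export
initial_strategies <- function(net, defectors = character()) {
  s <- rep("C", n_nodes(net))
  if (length(defectors)) s[node_index(net, defectors)] <- "D"
  s
}

# 2x2 lookup matrix: rows own strategy (C=1, D=2), cols other strategy.
payoff_lookup <- function(m) {
  matrix(c(m$R, m$T, m$S, m$P), nrow = 2,
         dimnames = list(c("C", "D"), c("C", "D")))
}

#' Per-node payoffs for one round of play
#'
#' Every node plays the pairwise game with each neighbor over the
#' incident edges and accumulates (not degree-normalizes) the payoffs.
#' With `weight_mode = TRUE` each edge "fires" this round with
#' probability `min(1, weight)`, drawn once per edge so both endpoints
#' see the same event; a non-firing edge contributes nothing to either
#' endpoint. Weights above 1 are clamped to probability 1 with a
#' warning. Payoffs carry no memory across rounds.
#'
#' Uses the current RNG stream (one `runif(n_edges)` block per call)
#' when `weight_mode` is on.
#'
#' @param net a [network()] object.
#' @param s strategy vector aligned to node order (`"C"`/`"D"`).
#' @param m a [payoff_matrix()].
#' @param weight_mode read edge weights as per-round play probabilities.
#' @return numeric payoff vector named by node label.
#' @export
round_payoffs <- function(net, s, m, weight_mode = FALSE) {
  n <- n_nodes(net)
  if (length(s) != n) stop("strategy vector does not match network size")
  si <- match(s, c("C", "D"))
  if (anyNA(si)) stop("strategies must be \"C\" or \"D\"")
  e <- net$edges
  if (weight_mode && nrow(e)) {
    if (any(e$weight > 1))
      warning("edge weights > 1 clamped to play probability 1")
    fired <- stats::runif(nrow(e)) < pmin(1, e$weight)
    e <- e[fired, , drop = FALSE]
  }
  pay <- numeric(n)
  if (nrow(e)) {
    look <- payoff_lookup(m)
    ends <- c(e$from, e$to)
    opp <- c(e$to, e$from)
    contrib <- look[cbind(si[ends], si[opp])]
    acc <- rowsum(contrib, group = ends)
    pay[as.integer(rownames(acc))] <- acc[, 1]
  }
  names(pay) <- net$labels
  pay
}
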