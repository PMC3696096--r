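#' Goodman-Kruskal gamma rank association
#'
#' Counts, over all unordered index pairs, the concordant pairs (x and y
#' order agree, neither tied) and discordant pairs, and returns
#' `gamma = (C - D) / (C + D)`. Ties contribute to neither count, which
#' is why gamma suits heavily tied rankings such as degree tables. The
#' standard error is the Goodman-Kruskal asymptotic estimator; the
#' two-sided p-value uses the null-hypothesis (gamma = 0) asymptotic
#' standard error with a normal approximation.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return object of class `gk_gamma`: `gamma`, `se`, `p_value`,
#'   `concordant`, `discordant`, `n`.
#' @export
#' @examples
#' goodman_kruskal_gamma(c(1, 2, 3, 4), c(1, 3, 2, 4))$gamma  # 4/6
goodman_kruskal_gamma <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 2) stop("need at least 2 observations")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  agree <- sx * sy
  ci <- rowSums(agree == 1)   # concordant partners of each observation
  di <- rowSums(agree == -1)  # discordant partners
  C <- sum(ci) / 2
  D <- sum(di) / 2
  if (C + D == 0) stop("gamma undefined: all pairs tied")
  g <- (C - D) / (C + D)
  se <- 2 / (C + D)^2 * sqrt(sum((D * ci - C * di)^2))
  v0 <- sum((ci - di)^2) - 4 * (C - D)^2 / n
  se0 <- if (v0 > 0) sqrt(v0) / (C + D) else 0
  p <- if (se0 > 0) 2 * stats::pnorm(-abs(g / se0)) else as.numeric(g == 0)
  structure(list(gamma = g, se = se, p_value = p,
                 concordant = C, discordant = D, n = n),
            class = "gk_gamma")
}

#' @export
print.gk_gamma <- function(x, ...) {
  cat(sprintf("Goodman-Kruskal gamma = %.4f +/- %.4f (C = %d, D = %d, p = %.3g)\n",
              x$gamma, x$se, x$concordant, x$discordant, x$p_value))
  invisible(x)
}

#' Two-sample chi-square comparison of GC distributions
#'
#' Bins both samples on a shared equal-width grid over [0, 1], pools
#' adjacent sparse bins until every expected count is at least 5, and
#' runs the two-sample homogeneity chi-square (no continuity
#' correction).
#'
#' @param dist_a,dist_b numeric samples of game-centrality values in
#'   [0, 1].
#' @param bins number of equal-width bins before pooling (default 10).
#' @return list with `chi2`, `df`, `p`, `table` (2 x k pooled counts).
#' @export
chi_square_gc <- function(dist_a, dist_b, bins = 10L) {
  if (!length(dist_a) || !length(dist_b)) stop("samples must be nonempty")
  vals <- c(dist_a, dist_b)
  if (any(vals < 0 | vals > 1)) stop("GC values must lie in [0, 1]")
  breaks <- seq(0, 1, length.out = bins + 1L)
  cnt <- function(v) as.vector(table(cut(v, breaks, include.lowest = TRUE)))
  tab <- rbind(a = cnt(dist_a), b = cnt(dist_b))
  # pool adjacent bins while any expected count < 5
  repeat {
    if (ncol(tab) < 2L) stop("all mass in one pooled bin")
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    bad <- which(apply(expected, 2, min) < 5)
    if (!length(bad)) break
    j <- bad[1]
    k <- if (j == ncol(tab)) j - 1L else j + 1L
    tab[, min(j, k)] <- tab[, j] + tab[, k]
    tab <- tab[, -max(j, k), drop = FALSE]
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value), table = tab)
}

#' Mean and standard error
#'
#' @param values numeric vector.
#' @return list with `mean` and `sem` (`NA` for a single value).
#' @export
mean_sem <- function(values) {
  n <- length(values)
  if (n < 1) stop("empty input")
  list(mean = mean(values),
       sem = if (n >= 2) stats::sd(values) / sqrt(n) else NA_real_)
}

#' Compare two dependent correlations sharing a variable
#'
#' Williams' t test (Steiger's recommendation) for whether
#' cor(x1, y) differs from cor(x2, y) given cor(x1, x2), on n
#' observations. Used to ask whether one predictor correlates with an
#' outcome significantly better than another measured on the same
#' cases.
#'
#' @param r12,r13 the two correlations with the shared variable.
#' @param r23 the correlation between the two predictors.
#' @param n sample size (> 3).
#' @return list with `t`, `df`, `p_value` (two-sided).
#' @export
compare_dependent_cors <- function(r12, r13, r23, n) {
  stopifnot(n > 3, abs(r12) <= 1, abs(r13) <= 1, abs(r23) <= 1)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  tval <- (r12 - r13) * sqrt((n - 1) * (1 + r23) /
            (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
  df <- n - 3
  list(t = tval, df = df, p_value = 2 * stats::pt(-abs(tval), df))
}
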