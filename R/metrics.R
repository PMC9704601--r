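#' Kendall rank correlation by strict pair counting
#'
#' Counts strictly concordant and strictly discordant pairs over all
#' \eqn{n(n-1)/2} unordered pairs; pairs tied in either list count toward
#' neither.  The default variant `"a"` uses the plain denominator
#' \eqn{n(n-1)/2}; variant `"b"` applies the usual tie correction
#' \eqn{\sqrt{(n_0 - t_x)(n_0 - t_y)}}.
#'
#' @param x,y paired numeric vectors (scores or ranks; any strictly
#'   increasing transform of either leaves the result unchanged).
#' @param variant `"a"` (default) or `"b"`.
#' @return a list of class `"rank_correlation"` with `tau`, `n_c`, `n_d`,
#'   `n`, `variant`.
#' @export
kendall_tau <- function(x, y, variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop("at least two paired observations are required")
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  ut <- upper.tri(sx)
  s <- sx[ut] * sy[ut]
  n_c <- sum(s > 0)
  n_d <- sum(s < 0)
  n0 <- n * (n - 1) / 2
  tau <- if (variant == "a") {
    (n_c - n_d) / n0
  } else {
    tx <- sum(sx[ut] == 0)
    ty <- sum(sy[ut] == 0)
    (n_c - n_d) / sqrt((n0 - tx) * (n0 - ty))
  }
  structure(list(tau = tau, n_c = n_c, n_d = n_d, n = n, variant = variant),
            class = "rank_correlation")
}

#' @export
print.rank_correlation <- function(x, ...) {
  cat(sprintf("Kendall tau-%s = %.4f  (n = %d, concordant %d, discordant %d)\n",
              x$variant, x$tau, x$n, x$n_c, x$n_d))
  invisible(x)
}

#' Monotonicity of a ranking
#'
#' \eqn{M(R) = (1 - \sum_r n_r (n_r - 1) / (n (n - 1)))^2}, where the
#' \eqn{n_r} are the sizes of the tie groups.  1 means all nodes receive
#' distinct ranks, 0 means all share one rank.  The statistic depends only
#' on group sizes, so it is invariant to the rank-labelling scheme, and
#' groups are formed on exact equality of the supplied scores or ranks.
#'
#' @param r numeric vector of ranks or scores (or an `electre_ranking` /
#'   `spread_power` object).
#' @return list of class `"monotonicity_report"` with `M`, `group_sizes`,
#'   `n`.
#' @export
monotonicity <- function(r) {
  if (inherits(r, "electre_ranking")) r <- r$score
  if (inherits(r, "spread_power")) r <- r$spread
  r <- as.numeric(r)
  n <- length(r)
  if (n < 2L) stop("at least two ranked nodes are required")
  sizes <- as.integer(table(r))
  M <- (1 - sum(sizes * (sizes - 1)) / (n * (n - 1)))^2
  structure(list(M = M, group_sizes = sort(sizes, decreasing = TRUE), n = n),
            class = "monotonicity_report")
}

#' @export
print.monotonicity_report <- function(x, ...) {
  cat(sprintf("monotonicity M = %.4f  (n = %d, %d rank groups, largest %d)\n",
              x$M, x$n, length(x$group_sizes), max(x$group_sizes)))
  invisible(x)
}

# coerce rankings of several shapes to data.frame(node, score)
.as_node_scores <- function(x) {
  if (inherits(x, "electre_ranking")) {
    return(data.frame(node = x$nodes, score = unname(x$score)))
  }
  if (inherits(x, "spread_power")) {
    return(data.frame(node = x$node, score = x$spread))
  }
  if (is.data.frame(x)) {
    sc <- intersect(c("score", "spread"), names(x))[1L]
    stopifnot("node" %in% names(x), !is.na(sc))
    return(data.frame(node = x$node, score = x[[sc]]))
  }
  if (is.numeric(x) && !is.null(names(x))) {
    return(data.frame(node = as.integer(names(x)), score = unname(x)))
  }
  stop("cannot interpret ranking; supply a named score vector or a ",
       "data.frame with columns node and score")
}

#' Jaccard similarity of two top-c node sets
#'
#' \eqn{J_c = |X(c) \cap Y(c)| / |X(c) \cup Y(c)|}, where \eqn{X(c)} holds
#' the nodes in the first `c` positions of a ranking.  Ties at the cutoff
#' are resolved deterministically by smallest node label, so repeated calls
#' always compare the same sets.
#'
#' @param x,y rankings (named score vectors, `electre_ranking` or
#'   `spread_power` objects, or data.frames with `node` and `score`).
#' @param c cutoff, `1 <= c <= n`.
#' @return list of class `"topc_similarity"` with `c`, `jaccard`, `x_top`,
#'   `y_top`.
#' @export
jaccard_top_c <- function(x, y, c) {
  xs <- .as_node_scores(x)
  ys <- .as_node_scores(y)
  if (!setequal(xs$node, ys$node)) stop("rankings cover different node sets")
  n <- nrow(xs)
  if (c < 1 || c > n) stop("c must lie between 1 and ", n)
  top <- function(df) df$node[order(-df$score, df$node)][seq_len(c)]
  xt <- top(xs)
  yt <- top(ys)
  structure(list(c = c,
                 jaccard = length(intersect(xt, yt)) / length(union(xt, yt)),
                 x_top = xt, y_top = yt),
            class = "topc_similarity")
}

#' @export
print.topc_similarity <- function(x, ...) {
  cat(sprintf("top-%d Jaccard similarity = %.4f\n", x$c, x$jaccard))
  invisible(x)
}

#' Select the criteria most correlated with simulated spreading
#'
#' Computes the Kendall correlation of every criterion column against the
#' spreading-power reference ranking and returns the `k` best, the
#' attribute-subset selection step that precedes the ELECTRE ranking.
#' Ties are broken by column order.
#'
#' @param ft feature table.
#' @param sigma spreading-power reference (a [spread_power()] object, named
#'   vector, or data.frame with `node` and `score`/`spread`).
#' @param k number of criteria to keep.
#' @param criteria candidate columns; defaults to every column of `ft`
#'   except `node` and `sir_spread`.
#' @param variant Kendall variant, see [kendall_tau()].
#' @return list of class `"feature_selection"` with `selected` (the chosen
#'   names, best first) and `tau` (all correlations, sorted).
#' @export
select_features <- function(ft, sigma, k = 5L,
                            criteria = setdiff(names(ft), c("node", "sir_spread")),
                            variant = "a") {
  sg <- .as_node_scores(sigma)
  idx <- match(ft$node, sg$node)
  if (anyNA(idx)) stop("sigma does not cover all nodes of the feature table")
  if (k < 1 || k > length(criteria)) stop("k must lie between 1 and ", length(criteria))
  y <- sg$score[idx]
  taus <- vapply(criteria, function(cr) kendall_tau(ft[[cr]], y, variant)$tau, 1)
  ord <- order(-taus)   # stable: ties keep column order
  structure(list(selected = criteria[ord][seq_len(k)], tau = taus[ord]),
            class = "feature_selection")
}

#' @export
print.feature_selection <- function(x, ...) {
  cat("criteria by Kendall correlation with spreading power:\n")
  print(round(x$tau, 4))
  cat("selected:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
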