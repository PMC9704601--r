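#' Build a decision matrix from a feature table
#'
#' @param ft a feature table (data.frame with a `node` column).
#' @param criteria character vector of criterion column names to use.
#' @param orientations named character vector mapping criteria to
#'   `"benefit"` (higher is better) or `"cost"`; criteria not named are
#'   benefit-type, the convention for all structural spreading indices.
#' @return a numeric matrix (nodes x criteria) with node labels as rownames
#'   and an `orientations` attribute.
#' @export
build_decision_matrix <- function(ft, criteria, orientations = NULL) {
  missing_cr <- setdiff(criteria, names(ft))
  if (length(missing_cr)) {
    stop("criteria not present in feature table: ",
         paste(missing_cr, collapse = ", "))
  }
  if (nrow(ft) < 2L) stop("at least two alternatives (nodes) are required")
  if (length(criteria) < 1L) stop("at least one criterion is required")
  x <- as.matrix(ft[, criteria, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- as.character(ft$node)
  orient <- rep("benefit", length(criteria))
  names(orient) <- criteria
  if (!is.null(orientations)) {
    bad <- setdiff(names(orientations), criteria)
    if (length(bad)) stop("orientation given for unknown criterion: ",
                          paste(bad, collapse = ", "))
    stopifnot(all(orientations %in% c("benefit", "cost")))
    orient[names(orientations)] <- orientations
  }
  attr(x, "orientations") <- orient
  x
}

#' Column-wise vector normalisation of a decision matrix
#'
#' Each criterion column is divided by its Euclidean norm, so every column
#' of the result has unit norm and the procedure is invariant to positive
#' rescaling of any criterion.
#'
#' @param x decision matrix from [build_decision_matrix()].
#' @return matrix of the same shape.
#' @export
normalize_decision <- function(x) {
  norms <- sqrt(colSums(x^2))
  zero <- norms == 0
  if (any(zero)) {
    stop("criterion column(s) are all zero and cannot be normalised: ",
         paste(colnames(x)[zero], collapse = ", "))
  }
  r <- sweep(x, 2L, norms, "/")
  attr(r, "orientations") <- attr(x, "orientations")
  r
}

#' Shannon-entropy criterion weights
#'
#' The standard entropy-weight method on the raw (non-negative) decision
#' matrix: column shares \eqn{p_{ij} = x_{ij} / \sum_i x_{ij}}, entropies
#' \eqn{E_j = -\frac{1}{\ln m} \sum_i p_{ij} \ln p_{ij}} (with
#' \eqn{0 \ln 0 = 0}), divergences \eqn{d_j = 1 - E_j} and weights
#' \eqn{w_j = d_j / \sum d_j}.  A criterion that is constant across nodes
#' carries no information and receives weight 0; if every criterion is
#' constant the weights fall back to uniform.
#'
#' @param x non-negative decision matrix.
#' @return numeric weight vector summing to 1, named by criterion.
#' @export
entropy_weights <- function(x) {
  if (any(x < 0)) stop("entropy weights require a non-negative decision matrix")
  m <- nrow(x)
  p <- sweep(x, 2L, colSums(x), "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  E <- -colSums(plogp) / log(m)
  d <- 1 - E
  w <- if (sum(d) > 0) d / sum(d) else rep(1 / ncol(x), ncol(x))
  setNames(as.numeric(w), colnames(x))
}

#' Weighted normalised decision matrix
#'
#' @param r normalised matrix from [normalize_decision()].
#' @param w weight vector.
#' @return matrix `v` with `v[i, j] = w[j] * r[i, j]`.
#' @export
weighted_matrix <- function(r, w) {
  v <- sweep(r, 2L, w, "*")
  attr(v, "orientations") <- attr(r, "orientations")
  v
}

# one block of rows of the pairwise concordance / discordance matrices
.pairwise_block <- function(v, w, benefit, rows) {
  m <- nrow(v)
  B <- length(rows)
  C <- matrix(0, B, m)
  num <- matrix(0, B, m)
  den <- matrix(0, B, m)
  for (j in seq_len(ncol(v))) {
    diff <- outer(v[rows, j], v[, j], "-")
    if (!benefit[j]) diff <- -diff
    conc <- diff >= 0
    C <- C + w[j] * conc
    ad <- abs(diff)
    den <- pmax(den, ad)
    ad[conc] <- 0
    num <- pmax(num, ad)
  }
  D <- matrix(0, B, m)
  pos <- den > 0
  D[pos] <- num[pos] / den[pos]
  idx <- cbind(seq_len(B), rows)
  C[idx] <- 0
  D[idx] <- 0
  list(C = C, D = D)
}

#' Pairwise concordance and discordance matrices
#'
#' For every ordered pair (k, e) of alternatives, the concordance
#' \eqn{C_{ke}} sums the weights of the criteria on which k is at least as
#' good as e, and the discordance \eqn{d_{ke}} is the largest opposing
#' weighted gap divided by the largest weighted gap on any criterion
#' (0 when the rows are identical or no criterion opposes).  Diagonals are 0.
#'
#' @param v weighted normalised matrix (with orientations attribute).
#' @param w weight vector.
#' @return list with matrices `C` and `D`.
#' @export
concordance_discordance <- function(v, w) {
  orient <- attr(v, "orientations")
  benefit <- if (is.null(orient)) rep(TRUE, ncol(v)) else orient == "benefit"
  res <- .pairwise_block(v, w, benefit, seq_len(nrow(v)))
  dimnames(res$C) <- dimnames(res$D) <- list(rownames(v), rownames(v))
  res
}

#' Dominance model from concordance / discordance matrices
#'
#' Thresholds are the off-diagonal means \eqn{\bar c} and \eqn{\bar d}
#' (denominator \eqn{m(m-1)}).  Concordant dominance requires
#' \eqn{C_{ke} \ge \bar c}; discordant dominance requires, under the default
#' `eq10 = "le"`, \eqn{d_{ke} \le \bar d} -- a pair dominates when its
#' opposition is *below* the typical level.  The final dominance matrix is
#' the elementwise product and the net score of an alternative is its row
#' sum minus its column sum (dominations minus defeats), which always sums
#' to zero over all alternatives.
#'
#' @param cd list with `C` and `D` from [concordance_discordance()].
#' @param eq10 `"le"` (default) or `"ge"`: direction of the discordant
#'   threshold comparison, exposed for sensitivity analysis.
#' @return list with `c_bar`, `d_bar`, binary matrices `F`, `G`, `H`, and
#'   `net_score`.
#' @export
dominance <- function(cd, eq10 = c("le", "ge")) {
  eq10 <- match.arg(eq10)
  C <- cd$C
  D <- cd$D
  m <- nrow(C)
  off <- m * (m - 1)
  c_bar <- sum(C) / off
  d_bar <- sum(D) / off
  Fm <- (C >= c_bar) * 1
  Gm <- if (eq10 == "le") (D <= d_bar) * 1 else (D >= d_bar) * 1
  diag(Fm) <- 0
  diag(Gm) <- 0
  H <- Fm * Gm
  list(c_bar = c_bar, d_bar = d_bar, F = Fm, G = Gm, H = H,
       net_score = rowSums(H) - colSums(H))
}

#' Dense ranks from scores
#'
#' Higher score means better (smaller) rank; exactly equal scores share a
#' rank and ranks are dense (1..number of distinct scores).
#'
#' @param scores numeric vector, optionally named.
#' @return integer vector of ranks with the same names.
#' @export
dense_ranks <- function(scores) {
  u <- sort(unique(scores), decreasing = TRUE)
  setNames(match(scores, u), names(scores))
}

#' Rank influential nodes with the simplified ELECTRE procedure
#'
#' The package's core ranking engine.  Starting from a node-by-criterion
#' feature table it (1) forms the decision matrix, (2) normalises each
#' criterion to unit Euclidean norm, (3) derives criterion weights by the
#' Shannon entropy method (or takes user weights), (4) weights the
#' normalised matrix, (5--7) computes pairwise concordance and discordance,
#' (8--10) thresholds them at their off-diagonal means into a binary
#' dominance relation, and (11) scores each node by dominations minus
#' defeats.  Ties in the final score share a dense rank; no arbitrary
#' tie-breaking is applied.
#'
#' The pairwise stage is computed in row blocks so that only
#' `block_size * m` numbers are held at a time, which keeps the method
#' usable on graphs with tens of thousands of nodes; the full pairwise
#' matrices are stored on the returned object only when `m <= keep_matrices`.
#'
#' @param ft feature table (data.frame with `node` column), e.g. from
#'   [compute_feature_table()] or [karate_features()].
#' @param criteria criterion columns to use; default: the five indices
#'   selected by correlation with simulated spreading (hks, kshell_if,
#'   coreness_plus, gravity, erm).
#' @param orientations see [build_decision_matrix()].
#' @param weights `"entropy"` (default), `"uniform"`, or a numeric vector.
#' @param eq10 discordant-threshold direction, see [dominance()].
#' @param block_size rows per block in the pairwise stage.
#' @param keep_matrices store full pairwise matrices when the number of
#'   alternatives does not exceed this (for inspection via `summary`).
#' @return an object of class `"electre_ranking"`; see
#'   [print.electre_ranking()], [summary.electre_ranking()],
#'   [as.data.frame.electre_ranking()].
#' @examples
#' ft <- karate_features()
#' er <- electre_rank(ft)
#' head(as.data.frame(er))
#' @export
electre_rank <- function(ft,
                         criteria = c("hks", "kshell_if", "coreness_plus",
                                      "gravity", "erm"),
                         orientations = NULL,
                         weights = "entropy",
                         eq10 = c("le", "ge"),
                         block_size = 256L,
                         keep_matrices = 500L) {
  eq10 <- match.arg(eq10)
  cl <- match.call()
  x <- build_decision_matrix(ft, criteria, orientations)
  orient <- attr(x, "orientations")
  r <- normalize_decision(x)
  w <- if (identical(weights, "entropy")) {
    entropy_weights(x)
  } else if (identical(weights, "uniform")) {
    setNames(rep(1 / ncol(x), ncol(x)), colnames(x))
  } else {
    stopifnot(is.numeric(weights), length(weights) == ncol(x), all(weights >= 0))
    setNames(weights / sum(weights), colnames(x))
  }
  v <- weighted_matrix(r, w)
  m <- nrow(v)
  benefit <- orient == "benefit"
  blocks <- split(seq_len(m), ceiling(seq_len(m) / block_size))

  # pass 1: threshold means over off-diagonal entries
  sC <- 0
  sD <- 0
  for (rows in blocks) {
    blk <- .pairwise_block(v, w, benefit, rows)
    sC <- sC + sum(blk$C)
    sD <- sD + sum(blk$D)
  }
  off <- m * (m - 1)
  c_bar <- sC / off
  d_bar <- sD / off

  # pass 2: dominance row / column sums (and optionally the full matrices)
  keep <- m <= keep_matrices
  rowH <- numeric(m)
  colH <- numeric(m)
  Cfull <- if (keep) matrix(0, m, m) else NULL
  Dfull <- if (keep) matrix(0, m, m) else NULL
  Hfull <- if (keep) matrix(0, m, m) else NULL
  for (rows in blocks) {
    blk <- .pairwise_block(v, w, benefit, rows)
    Fb <- (blk$C >= c_bar) * 1
    Gb <- if (eq10 == "le") (blk$D <= d_bar) * 1 else (blk$D >= d_bar) * 1
    idx <- cbind(seq_along(rows), rows)
    Fb[idx] <- 0
    Gb[idx] <- 0
    Hb <- Fb * Gb
    rowH[rows] <- rowSums(Hb)
    colH <- colH + colSums(Hb)
    if (keep) {
      Cfull[rows, ] <- blk$C
      Dfull[rows, ] <- blk$D
      Hfull[rows, ] <- Hb
    }
  }
  net <- setNames(rowH - colH, rownames(v))
  structure(list(
    call = cl,
    nodes = ft$node,
    criteria = colnames(x),
    orientations = orient,
    x = x, r = r, w = w, v = v,
    c_bar = c_bar, d_bar = d_bar,
    concordance = Cfull, discordance = Dfull, dominance = Hfull,
    eq10 = eq10,
    score = net,
    rank = dense_ranks(net)
  ), class = "electre_ranking")
}

#' @export
print.electre_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("ELECTRE ranking of %d nodes on %d criteria (%s)\n",
              length(x$score), length(x$criteria),
              paste(x$criteria, collapse = ", ")))
  cat(sprintf("thresholds: c_bar = %.4f, d_bar = %.4f\n", x$c_bar, x$d_bar))
  df <- as.data.frame(x)
  cat(sprintf("top %d of %d:\n", min(n, nrow(df)), nrow(df)))
  print(utils::head(df, n), row.names = FALSE)
  invisible(x)
}

#' @export
summary.electre_ranking <- function(object, ...) {
  df <- as.data.frame(object)
  ties <- table(object$rank)
  structure(list(
    n = length(object$score),
    criteria = object$criteria,
    weights = object$w,
    c_bar = object$c_bar, d_bar = object$d_bar,
    n_distinct_ranks = length(unique(object$rank)),
    monotonicity = monotonicity(object$rank)$M,
    largest_tie_group = max(ties),
    top = utils::head(df, 10L)
  ), class = "summary.electre_ranking")
}

#' @export
print.summary.electre_ranking <- function(x, ...) {
  cat(sprintf("ELECTRE ranking: %d nodes, %d distinct ranks, monotonicity %.4f\n",
              x$n, x$n_distinct_ranks, x$monotonicity))
  cat("entropy weights:\n")
  print(round(x$weights, 4))
  cat(sprintf("thresholds: c_bar = %.4f, d_bar = %.4f\n", x$c_bar, x$d_bar))
  cat("top-ranked nodes:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' Ranking as a data frame
#'
#' @param x an `electre_ranking` object.
#' @param ... unused.
#' @return data.frame with columns `node`, `score`, `rank`, ordered by
#'   (rank, node).
#' @export
as.data.frame.electre_ranking <- function(x, ...) {
  df <- data.frame(node = x$nodes, score = unname(x$score),
                   rank = unname(x$rank))
  df[order(df$rank, df$node), , drop = FALSE]
}

#' Plot a dominance-score profile
#'
#' Net dominance score against rank position, marking tie groups.
#'
#' @param x an `electre_ranking` object.
#' @param ... passed to [plot()].
#' @export
plot.electre_ranking <- function(x, ...) {
  df <- as.data.frame(x)
  plot(seq_len(nrow(df)), df$score, type = "s",
       xlab = "rank position", ylab = "net dominance score",
       main = "ELECTRE net dominance profile", ...)
  invisible(x)
}
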