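#' k-shell decomposition with an iteration trace
#'
#' Standard k-core peeling: starting from the minimum residual degree, every
#' pass simultaneously removes all nodes whose residual degree does not
#' exceed the current core index, and a node's shell is the core index at
#' which it is removed.  Beyond the shell index the trace records, for each
#' node, the global pass (iteration) at which it was removed, its iteration
#' counted within its own shell, and the number of passes its shell took --
#' the quantities the iteration-factor and hierarchical indices build on.
#'
#' @param g an undirected igraph graph.
#' @return a list of class `"kshell_trace"`:
#'   \describe{
#'     \item{shell}{named integer, the k-shell index of each node;}
#'     \item{removal_iteration}{named integer, global 1-based pass of removal;}
#'     \item{total_iterations}{number of passes overall;}
#'     \item{shell_iteration}{named integer, pass counted within the node's shell;}
#'     \item{shell_passes}{named integer, how many passes the node's shell took;}
#'     \item{theta}{named numeric, the iteration-refined shell value
#'       \eqn{ks (1 + m/n)} with `m = shell_iteration`, `n = shell_passes`.}
#'   }
#' @export
k_shell <- function(g) {
  ids <- .node_ids(g)
  n <- length(ids)
  adj <- .adj_index_list(g)
  res <- vapply(adj, length, 1L)
  alive <- rep(TRUE, n)
  shell <- integer(n)
  iter <- integer(n)
  k <- 0L
  pass <- 0L
  while (any(alive)) {
    k <- max(k, min(res[alive]))
    batch <- which(alive & res <= k)
    pass <- pass + 1L
    shell[batch] <- k
    iter[batch] <- pass
    alive[batch] <- FALSE
    for (v in batch) {
      nb <- adj[[v]]
      nb <- nb[alive[nb]]
      res[nb] <- res[nb] - 1L
    }
  }
  # per-shell iteration bookkeeping
  m_within <- integer(n)
  n_shell <- integer(n)
  for (s in unique(shell)) {
    in_s <- shell == s
    passes <- sort(unique(iter[in_s]))
    m_within[in_s] <- match(iter[in_s], passes)
    n_shell[in_s] <- length(passes)
  }
  nm <- as.character(ids)
  structure(list(
    shell = setNames(shell, nm),
    removal_iteration = setNames(iter, nm),
    total_iterations = pass,
    shell_iteration = setNames(m_within, nm),
    shell_passes = setNames(n_shell, nm),
    theta = setNames(shell * (1 + m_within / pmax(n_shell, 1L)), nm)
  ), class = "kshell_trace")
}

#' @export
print.kshell_trace <- function(x, ...) {
  cat(sprintf("k-shell decomposition: %d nodes, shells %d..%d, %d passes\n",
              length(x$shell), min(x$shell), max(x$shell), x$total_iterations))
  invisible(x)
}

#' Mixed degree decomposition
#'
#' Iterative peeling by the mixed degree \eqn{k_m(i) = k_r(i) + \lambda
#' k_s(i)}, where \eqn{k_r} counts edges to nodes still present and
#' \eqn{k_s} edges to nodes already removed.  Every pass removes all nodes at
#' the current minimum mixed degree; a node's score is its mixed degree at
#' removal.  With \eqn{\lambda = 1} the score equals the original degree, and
#' with \eqn{\lambda = 0} it is the residual degree at removal of plain
#' k-core peeling.
#'
#' @param g an undirected igraph graph.
#' @param lambda weight of removed edges, in `[0, 1]`; default 0.7.
#' @return named numeric vector of mixed-degree scores.
#' @export
mdd <- function(g, lambda = 0.7) {
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  ids <- .node_ids(g)
  n <- length(ids)
  adj <- .adj_index_list(g)
  deg <- vapply(adj, length, 1L)
  kr <- deg
  alive <- rep(TRUE, n)
  val <- numeric(n)
  eps <- 1e-9
  while (any(alive)) {
    km <- kr + lambda * (deg - kr)
    mn <- min(km[alive])
    batch <- which(alive & km <= mn + eps)
    val[batch] <- km[batch]
    alive[batch] <- FALSE
    for (v in batch) {
      nb <- adj[[v]]
      nb <- nb[alive[nb]]
      kr[nb] <- kr[nb] - 1L
    }
  }
  setNames(val, as.character(ids))
}
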