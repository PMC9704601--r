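# shared oracles and fixtures, independent of the implementation under test

# brute-force Kendall pair counter (double loop, no vectorisation)
tau_bruteforce <- function(x, y) {
  n <- length(x)
  nc <- 0L
  nd <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- (x[i] - x[j]) * (y[i] - y[j])
      if (s > 0) nc <- nc + 1L else if (s < 0) nd <- nd + 1L
    }
  }
  (nc - nd) / (n * (n - 1) / 2)
}

# exhaustive k-core oracle: a node's shell is the largest k such that the
# node survives repeated deletion of all nodes with degree < k
core_bruteforce <- function(g) {
  ids <- as.integer(igraph::V(g)$name)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  n <- length(adj)
  shell <- integer(n)
  for (k in seq_len(n)) {
    alive <- rep(TRUE, n)
    repeat {
      deg <- vapply(seq_len(n), function(i) {
        if (!alive[i]) return(-1L)
        sum(alive[adj[[i]]])
      }, 1L)
      drop <- which(alive & deg < k)
      if (!length(drop)) break
      alive[drop] <- FALSE
    }
    shell[alive] <- k
    if (!any(alive)) break
  }
  stats::setNames(shell, as.character(ids))
}

# residual-degree-at-removal peeling oracle (min-batch, like MDD at lambda 0)
residual_peel_oracle <- function(g) {
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  n <- length(adj)
  alive <- rep(TRUE, n)
  val <- numeric(n)
  while (any(alive)) {
    res <- vapply(seq_len(n), function(i) {
      if (!alive[i]) return(Inf)
      sum(alive[adj[[i]]])
    }, 1)
    mn <- min(res[alive])
    batch <- which(alive & res <= mn)
    val[batch] <- res[batch]
    alive[batch] <- FALSE
  }
  stats::setNames(val, igraph::V(g)$name)
}

# structurally equivalent node groups of the karate club: every structural
# index must give identical values within each group
karate_automorphic_groups <- list(c(5, 11), c(6, 7), c(18, 22),
                                  c(15, 16, 19, 21, 23))

# relabel a graph by a node permutation, keeping original labels as names
relabel_graph <- function(g, perm) {
  igraph::permute(g, perm)
}

expect_constant_within_groups <- function(values, groups) {
  for (grp in groups) {
    v <- values[as.character(grp)]
    expect_equal(max(v) - min(v), 0,
                 info = paste("group", paste(grp, collapse = ",")))
  }
}
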