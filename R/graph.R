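#' spreadrank: multi-attribute ranking of influential spreaders
#'
#' Tools for scoring and ranking the spreading power of nodes in undirected,
#' unweighted networks.  Nine local and semi-local structural indices are
#' combined through a simplified ELECTRE outranking procedure weighted by
#' Shannon entropy; SIR epidemic simulation provides the ground-truth
#' spreading power against which indices and rankings are evaluated with
#' Kendall correlation, top-c Jaccard similarity and a monotonicity statistic.
#'
#' Graphs are plain \pkg{igraph} objects whose vertices carry integer labels
#' in the \code{name} attribute; every exported function accepts and returns
#' them in that form.
#'
#' @keywords internal
#' @importFrom stats runif setNames
#' @importFrom utils read.table write.table
"_PACKAGE"

.node_ids <- function(g) {
  nm <- igraph::vertex_attr(g, "name")
  if (is.null(nm)) seq_len(igraph::vcount(g)) else as.integer(nm)
}

.adj_index_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
}

#' Read an undirected network from a two-column edge list
#'
#' Parses the plain-text format used throughout the package: one edge per
#' line, two integer node labels separated by whitespace or tabs.  Blank
#' lines and lines starting with \code{#} are skipped.  Duplicate edges
#' (including reversed duplicates) are collapsed and self-loops are dropped
#' with a warning, so the result is always a simple undirected graph.
#'
#' @param path file path, or a character vector of lines (useful in tests).
#' @return an undirected simple \pkg{igraph} graph; vertex names are the node
#'   labels from the file, ordered increasingly.
#' @export
read_edge_list <- function(path) {
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path) else as.character(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad)) {
    stop("malformed edge on line ", lineno[bad[1L]], ": fewer than two fields")
  }
  ends <- t(vapply(toks, function(tk) tk[1:2], character(2)))
  num <- suppressWarnings(matrix(as.integer(ends), ncol = 2L))
  frac <- suppressWarnings(matrix(as.numeric(ends) %% 1 != 0, ncol = 2L))
  bad <- which(rowSums(is.na(num)) > 0 | rowSums(frac, na.rm = TRUE) > 0)
  if (length(bad)) {
    stop("malformed edge on line ", lineno[bad[1L]], ": non-integer node label '",
         paste(ends[bad[1L], ], collapse = " "), "'")
  }
  loops <- num[, 1L] == num[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    num <- num[!loops, , drop = FALSE]
  }
  ids <- sort(unique(as.vector(num)))
  g <- igraph::graph_from_edgelist(
    matrix(match(num, ids), ncol = 2L), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  igraph::set_vertex_attr(g, "name", value = as.character(ids))
}

#' Write a graph as a two-column edge list
#'
#' Inverse of [read_edge_list()]: one line per edge, source and target node
#' labels separated by a tab.
#'
#' @param g an undirected igraph graph.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  writeLines(paste(el[, 1L], el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' The Zachary karate-club network
#'
#' The canonical 34-node, 78-edge social network of a university karate club,
#' the standard benchmark for influential-spreader methods.  Node labels are
#' 1 to 34; node 34 has the maximum degree, 17.
#'
#' @return an undirected igraph graph with 34 vertices named "1".."34".
#' @export
karate_club <- function() {
  path <- system.file("extdata", "karate.edgelist", package = "spreadrank")
  read_edge_list(path)
}

#' Published karate-club decision matrix
#'
#' The node-by-criterion table for the karate club: the nine structural
#' indices plus the published SIR spreading power (column \code{sir_spread},
#' mean outbreak size at infection rate 0.15).  Values are as published;
#' see the package vignette for which columns the package reproduces exactly
#' and which are documented reconstructions.
#'
#' @return a data.frame with column \code{node} followed by the nine
#'   criterion columns and \code{sir_spread}.
#' @export
karate_features <- function() {
  path <- system.file("extdata", "karate_features.tsv", package = "spreadrank")
  read_feature_table(path)
}

#' Descriptive summary of a network
#'
#' Node and edge counts, maximum and mean degree, and degree assortativity
#' (the Pearson correlation of end-point degrees over all edges, counted in
#' both orientations).  Assortativity is `NA` when the graph has no edges or
#' constant degree.
#'
#' @param g an undirected igraph graph with at least one node.
#' @return a list of class `"network_summary"` with elements `n_nodes`,
#'   `n_edges`, `max_degree`, `mean_degree`, `assortativity`.
#' @export
network_summary <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0L) stop("empty graph")
  deg <- igraph::degree(g)
  assort <- if (igraph::ecount(g) == 0L || stats::var(deg) == 0) {
    NA_real_
  } else {
    igraph::assortativity_degree(g, directed = FALSE)
  }
  structure(list(
    n_nodes = n,
    n_edges = igraph::ecount(g),
    max_degree = if (n) max(deg) else 0L,
    mean_degree = 2 * igraph::ecount(g) / n,
    assortativity = assort
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  cat(sprintf("degree: max %d, mean %.4f\n", x$max_degree, x$mean_degree))
  cat(sprintf("assortativity: %s\n",
              if (is.na(x$assortativity)) "undefined (constant degree)"
              else sprintf("%.5f", x$assortativity)))
  invisible(x)
}

.name_1n <- function(g) {
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g))))
}

#' Synthetic test networks
#'
#' Deterministic and random graph families used for property testing:
#' a star (`leaves` spokes around node 1), a path, a cycle, a complete graph,
#' an Erdos-Renyi \eqn{G(n,p)} graph and a Barabasi-Albert preferential
#' attachment graph.  Random families require a seed and are reproducible
#' for a fixed seed.  Vertices are named 1..n.
#'
#' @param leaves,n number of leaves / nodes.
#' @param p edge probability in `[0, 1]`.
#' @param m edges attached per step, `m < n`.
#' @param seed integer RNG seed (required for random families).
#' @return an undirected igraph graph.
#' @name synthetic_graphs
NULL

#' @rdname synthetic_graphs
#' @export
graph_star <- function(leaves) {
  stopifnot(leaves >= 1)
  .name_1n(igraph::make_star(leaves + 1L, mode = "undirected", center = 1L))
}

#' @rdname synthetic_graphs
#' @export
graph_path <- function(n) {
  stopifnot(n >= 2)
  .name_1n(igraph::make_ring(n, circular = FALSE))
}

#' @rdname synthetic_graphs
#' @export
graph_cycle <- function(n) {
  stopifnot(n >= 3)
  .name_1n(igraph::make_ring(n, circular = TRUE))
}

#' @rdname synthetic_graphs
#' @export
graph_complete <- function(n) {
  stopifnot(n >= 1)
  .name_1n(igraph::make_full_graph(n))
}

.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' @rdname synthetic_graphs
#' @export
graph_erdos_renyi <- function(n, p, seed) {
  if (missing(seed)) stop("seed is required for random graph families")
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  .name_1n(.with_seed(seed, igraph::sample_gnp(n, p)))
}

#' @rdname synthetic_graphs
#' @export
graph_barabasi_albert <- function(n, m, seed) {
  if (missing(seed)) stop("seed is required for random graph families")
  if (m >= n || m < 1) stop("m must satisfy 1 <= m < n")
  .name_1n(.with_seed(
    seed, igraph::sample_pa(n, m = m, directed = FALSE)))
}
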