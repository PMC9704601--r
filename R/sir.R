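#' Monte-Carlo SIR spreading from a single seed
#'
#' Discrete-time susceptible-infected-recovered dynamics: the seed starts
#' infected and everything else susceptible; at every step each infected
#' node independently infects each susceptible neighbour with probability
#' `beta` (one Bernoulli trial per contact), then each infected node
#' recovers with probability `recovery_prob` (default 1: a one-step
#' infectious period, the convention of the k-shell spreading literature).
#' Updates are synchronous and infection attempts precede recovery within a
#' step.  A run ends when no infected nodes remain; its size is the number
#' of nodes ever infected, seed included.
#'
#' @param g an undirected igraph graph.
#' @param seed_node node label of the initially infected node.
#' @param beta per-contact infection probability in `[0, 1]`.
#' @param recovery_prob per-step recovery probability in `(0, 1]`.
#' @param runs number of Monte-Carlo repetitions.
#' @param rng_seed integer seed; results are bit-reproducible for a fixed
#'   seed.
#' @param return_runs if `TRUE`, also return the vector of per-run outbreak
#'   sizes.
#' @return a list with `mean` (the spreading power), `sd`, `se`, `runs`,
#'   and, if requested, `sizes`.
#' @export
simulate_sir <- function(g, seed_node, beta, recovery_prob = 1,
                         runs = 1000L, rng_seed = NULL,
                         return_runs = FALSE) {
  stopifnot(beta >= 0, beta <= 1, recovery_prob > 0, recovery_prob <= 1,
            runs >= 1)
  ids <- .node_ids(g)
  seed_idx <- match(as.integer(seed_node), ids)
  if (is.na(seed_idx)) stop("unknown seed node: ", seed_node)
  adj <- .adj_index_list(g)
  body <- function() {
    vapply(seq_len(runs), function(i) {
      .sir_run(adj, seed_idx, beta, recovery_prob)
    }, 1)
  }
  sizes <- if (is.null(rng_seed)) body() else .with_seed(rng_seed, body())
  out <- list(mean = mean(sizes), sd = stats::sd(sizes),
              se = stats::sd(sizes) / sqrt(runs), runs = runs,
              beta = beta, recovery_prob = recovery_prob)
  if (return_runs) out$sizes <- sizes
  out
}

.sir_run <- function(adj, seed_idx, beta, recovery_prob) {
  n <- length(adj)
  status <- integer(n)           # 0 susceptible, 1 infected, 2 recovered
  status[seed_idx] <- 1L
  infected <- seed_idx
  while (length(infected)) {
    contacts <- unlist(adj[infected], use.names = FALSE)
    contacts <- contacts[status[contacts] == 0L]
    new <- if (length(contacts)) {
      unique(contacts[runif(length(contacts)) < beta])
    } else integer(0)
    rec <- if (recovery_prob >= 1) infected else
      infected[runif(length(infected)) < recovery_prob]
    status[rec] <- 2L
    status[new] <- 1L
    infected <- c(infected[!(infected %in% rec)], new)
  }
  sum(status != 0L)
}

#' Deterministic SIR cascade on pre-drawn randomness
#'
#' With a one-step infectious period every directed contact (u, w) is
#' attempted at most once, so a single uniform draw per directed edge fully
#' determines a run: u infects w exactly when `draw(u, w) < beta`.  Running
#' the cascade on the *same* draws with a larger `beta` can only open more
#' contacts, so the final recovered set is monotone in `beta` -- exactly,
#' not just on average.  [sir_draws()] generates such a draw set.
#'
#' @param g an undirected igraph graph.
#' @param seed_node label of the initially infected node.
#' @param beta infection probability.
#' @param draws draw set from [sir_draws()] for the same graph.
#' @return integer vector of the labels of all ever-infected nodes.
#' @export
sir_cascade <- function(g, seed_node, beta, draws) {
  ids <- .node_ids(g)
  seed_idx <- match(as.integer(seed_node), ids)
  if (is.na(seed_idx)) stop("unknown seed node: ", seed_node)
  adj <- .adj_index_list(g)
  n <- length(adj)
  status <- integer(n)
  status[seed_idx] <- 1L
  infected <- seed_idx
  while (length(infected)) {
    new <- integer(0)
    for (u in infected) {
      for (w in adj[[u]]) {
        if (status[w] == 0L && draws$u[draws$key[u, w]] < beta) {
          new <- c(new, w)
        }
      }
    }
    new <- unique(new)
    status[infected] <- 2L
    status[new] <- 1L
    infected <- new
  }
  ids[status != 0L]
}

#' @rdname sir_cascade
#' @param rng_seed integer seed for the draw set.
#' @export
sir_draws <- function(g, rng_seed) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  key <- matrix(0L, n, n)
  ne <- nrow(el)
  key[el] <- seq_len(ne)
  key[el[, c(2, 1), drop = FALSE]] <- ne + seq_len(ne)
  u <- .with_seed(rng_seed, runif(2L * ne))
  list(key = key, u = u)
}

#' Spreading power of every node
#'
#' Runs [simulate_sir()] from every node in turn and ranks nodes by the
#' mean outbreak size, the usual Monte-Carlo ground truth ("sigma") that
#' structural indices are validated against.
#'
#' @inheritParams simulate_sir
#' @return an object of class `"spread_power"`: a data.frame with columns
#'   `node`, `spread` (mean outbreak size), `se`, and dense `rank`
#'   (ties share a rank).
#' @export
spread_power <- function(g, beta, recovery_prob = 1, runs = 1000L,
                         rng_seed = NULL) {
  ids <- .node_ids(g)
  seeds <- if (is.null(rng_seed)) rep(list(NULL), length(ids)) else
    as.list(rng_seed + seq_along(ids) - 1L)
  res <- mapply(function(v, s) {
    r <- simulate_sir(g, v, beta, recovery_prob, runs, rng_seed = s)
    c(r$mean, r$se)
  }, ids, seeds)
  df <- data.frame(node = ids, spread = res[1L, ], se = res[2L, ])
  df$rank <- unname(dense_ranks(df$spread))
  class(df) <- c("spread_power", "data.frame")
  attr(df, "beta") <- beta
  attr(df, "runs") <- runs
  df
}
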