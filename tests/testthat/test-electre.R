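pub <- karate_features()

test_that("decision matrix construction and validation", {
  x <- build_decision_matrix(pub, c("hks", "kshell_if", "coreness_plus",
                                    "gravity", "erm"))
  expect_equal(dim(x), c(34, 5))
  expect_equal(attr(x, "orientations"),
               setNames(rep("benefit", 5),
                        c("hks", "kshell_if", "coreness_plus", "gravity", "erm")))

  k4 <- compute_feature_table(graph_complete(4), "degree")
  x4 <- build_decision_matrix(k4, "degree")
  expect_equal(unname(x4[, 1]), rep(3, 4))

  expect_error(build_decision_matrix(pub, "closeness"), "not present")
  expect_error(build_decision_matrix(pub[1, ], "degree"), "two alternatives")
})

test_that("vector normalisation has unit columns and scale invariance", {
  x <- matrix(c(3, 4), ncol = 1, dimnames = list(NULL, "a"))
  expect_equal(unname(normalize_decision(x)[, 1]), c(0.6, 0.8))

  x5 <- build_decision_matrix(pub, c("hks", "kshell_if", "coreness_plus",
                                     "gravity", "erm"))
  r <- normalize_decision(x5)
  expect_equal(unname(colSums(r^2)), rep(1, 5), tolerance = 1e-12)

  # positive rescaling of a column changes nothing
  x5b <- x5
  x5b[, 2] <- x5b[, 2] * 1000
  expect_equal(normalize_decision(x5b), normalize_decision(x5),
               tolerance = 1e-12)

  xz <- matrix(c(1, 2, 0, 0), ncol = 2, dimnames = list(NULL, c("a", "b")))
  expect_error(normalize_decision(xz), "b")
})

test_that("entropy weights follow the divergence of each criterion", {
  # constant column carries no information
  x <- cbind(a = c(2, 2, 2), b = c(1, 2, 3))
  w <- entropy_weights(x)
  expect_equal(unname(w), c(0, 1))

  # identical columns share the weight uniformly
  x2 <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(unname(entropy_weights(x2)), c(0.5, 0.5))

  # hand-evaluated 2x2 case: rows (1,1) and (1,2)
  x3 <- cbind(a = c(1, 1), b = c(1, 2))
  expect_equal(unname(entropy_weights(x3)), c(0, 1))

  # every column constant: uniform fallback
  x4 <- cbind(a = c(2, 2), b = c(3, 3))
  expect_equal(unname(entropy_weights(x4)), c(0.5, 0.5))

  expect_error(entropy_weights(cbind(a = c(-1, 1))), "non-negative")
})

test_that("weighted matrix is the elementwise product", {
  r <- normalize_decision(cbind(a = c(3, 4), b = c(1, 1)))
  v <- weighted_matrix(r, c(0.5, 0.5))
  expect_equal(v, sweep(r, 2, c(0.5, 0.5), "*"))
  v0 <- weighted_matrix(r, c(1, 0))
  expect_equal(unname(v0[, 2]), c(0, 0))
})

test_that("concordance and discordance reproduce the hand-worked pair", {
  v <- rbind(k = c(0.5, 0.1), e = c(0.3, 0.2))
  colnames(v) <- c("a", "b")
  attr(v, "orientations") <- c(a = "benefit", b = "benefit")
  w <- c(0.6, 0.4)
  cd <- concordance_discordance(v, w)
  expect_equal(cd$C["k", "e"], 0.6)
  expect_equal(cd$C["e", "k"], 0.4)
  expect_equal(cd$D["k", "e"], 0.5)   # |0.1-0.2| / |0.5-0.3|
  expect_equal(cd$D["e", "k"], 1.0)

  # full dominance on every criterion: concordance 1, discordance 0
  v2 <- rbind(c(0.5, 0.4), c(0.3, 0.2))
  attr(v2, "orientations") <- c("benefit", "benefit")
  cd2 <- concordance_discordance(v2, c(0.5, 0.5))
  expect_equal(cd2$C[1, 2], 1)
  expect_equal(cd2$D[1, 2], 0)

  # identical rows: both concordances 1 (ties count), both discordances 0
  v3 <- rbind(c(0.2, 0.3), c(0.2, 0.3))
  attr(v3, "orientations") <- c("benefit", "benefit")
  cd3 <- concordance_discordance(v3, c(0.5, 0.5))
  expect_equal(cd3$C[1, 2], 1)
  expect_equal(cd3$C[2, 1], 1)
  expect_equal(cd3$D[1, 2], 0)
})

test_that("dominance thresholds and net scores follow the worked example", {
  v <- rbind(k = c(0.5, 0.1), e = c(0.3, 0.2))
  attr(v, "orientations") <- c("benefit", "benefit")
  cd <- concordance_discordance(v, c(0.6, 0.4))
  dm <- dominance(cd)
  expect_equal(dm$c_bar, 0.5)
  expect_equal(dm$d_bar, 0.75)
  expect_equal(dm$H["k", "e"], 1)
  expect_equal(dm$H["e", "k"], 0)
  expect_equal(unname(dm$net_score), c(1, -1))

  # identical alternatives: nobody dominates after F*G
  v3 <- rbind(c(0.2, 0.3), c(0.2, 0.3), c(0.2, 0.3))
  attr(v3, "orientations") <- c("benefit", "benefit")
  dm3 <- dominance(concordance_discordance(v3, c(0.5, 0.5)))
  expect_true(all(dm3$net_score == 0))
})

test_that("pairwise invariants hold on random decision matrices", {
  set.seed(21)
  for (rep in 1:3) {
    x <- matrix(runif(20 * 4, 0.1, 5), 20, 4,
                dimnames = list(1:20, letters[1:4]))
    r <- normalize_decision(build_decision_matrix(
      data.frame(node = 1:20, x), letters[1:4]))
    w <- entropy_weights(x)
    v <- weighted_matrix(r, w)
    cd <- concordance_discordance(v, w)
    off <- row(cd$C) != col(cd$C)
    # C_ke + C_ek >= 1, equality only without ties
    expect_true(all(cd$C[off] + t(cd$C)[off] >= 1 - 1e-12))
    expect_true(all(cd$D >= 0 & cd$D <= 1))
    dm <- dominance(cd)
    expect_equal(sum(dm$net_score), 0)
  }
})

test_that("the full ranking respects ties, scale invariance and ordering", {
  er <- electre_rank(pub)
  # automorphic nodes have identical feature rows, hence identical net
  # scores and a shared dense rank
  sc <- setNames(er$score, as.character(er$nodes))
  expect_constant_within_groups(sc, karate_automorphic_groups)
  rk <- setNames(er$rank, as.character(er$nodes))
  expect_constant_within_groups(rk, karate_automorphic_groups)
  # dense ranks: 1..K
  expect_equal(sort(unique(unname(er$rank))), seq_along(unique(er$score)))

  # positive rescaling of raw columns leaves the ranking unchanged
  pub2 <- pub
  pub2$hks <- pub2$hks * 1000
  pub2$erm <- pub2$erm / 77
  er2 <- electre_rank(pub2)
  expect_equal(er2$score, er$score)

  # permuting the node rows permutes but does not change the ranking
  set.seed(3)
  pub3 <- pub[sample(nrow(pub)), ]
  er3 <- electre_rank(pub3)
  expect_equal(er3$score[as.character(pub$node)],
               er$score[as.character(pub$node)])

  # a node strictly dominant on all criteria is ranked first
  ft <- data.frame(node = 1:4, a = c(9, 1, 2, 3), b = c(9, 3, 2, 1))
  expect_equal(as.data.frame(electre_rank(ft, c("a", "b")))$node[1], 1)
})

test_that("single-criterion ranking reduces to sorting by that criterion", {
  ft <- data.frame(node = 1:6, a = c(3, 1, 4, 1, 5, 9))
  er <- electre_rank(ft, "a", weights = "uniform")
  expect_equal(unname(er$rank), unname(dense_ranks(ft$a)))
})

test_that("blocked pairwise computation equals the direct one", {
  set.seed(14)
  ft <- data.frame(node = 1:80, matrix(runif(80 * 5, 0.1, 3), 80, 5))
  names(ft)[-1] <- paste0("c", 1:5)
  a <- electre_rank(ft, paste0("c", 1:5), block_size = 7)
  b <- electre_rank(ft, paste0("c", 1:5), block_size = 500)
  expect_equal(a$score, b$score)
  expect_equal(a$c_bar, b$c_bar)

  # composition of the exposed steps gives the same result
  x <- build_decision_matrix(ft, paste0("c", 1:5))
  w <- entropy_weights(x)
  v <- weighted_matrix(normalize_decision(x), w)
  dm <- dominance(concordance_discordance(v, w))
  expect_equal(unname(a$score), unname(dm$net_score))
})

test_that("the discordant-threshold direction flag changes the relation", {
  er_le <- electre_rank(pub, eq10 = "le")
  er_ge <- electre_rank(pub, eq10 = "ge")
  expect_false(identical(er_le$score, er_ge$score))
  expect_equal(sum(er_ge$score), 0)
})

test_that("cost-type criteria flip the concordance direction", {
  ft <- data.frame(node = 1:3, good = c(3, 2, 1), bad = c(1, 2, 3))
  er <- electre_rank(ft, c("good", "bad"),
                     orientations = c(bad = "cost"), weights = "uniform")
  expect_equal(as.data.frame(er)$node, c(1, 2, 3))
})

test_that("the blocked pairwise stage handles thousands of alternatives", {
  set.seed(41)
  m <- 1500
  ft <- data.frame(node = 1:m, matrix(runif(m * 5, 0.1, 3), m, 5))
  names(ft)[-1] <- paste0("c", 1:5)
  er <- electre_rank(ft, paste0("c", 1:5), block_size = 256)
  expect_equal(sum(er$score), 0)
  expect_null(er$concordance)   # full m x m matrices are not materialised
  expect_equal(length(er$score), m)
})
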