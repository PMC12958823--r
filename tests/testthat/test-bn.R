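test_that("Cholesky decorrelation matches hand calculations and inverts", {
  bv <- matrix(c(1, 1, 2, -1), 2, 2, dimnames = list(c("a", "b"), c("P", "Q")))
  K <- diag(2); dimnames(K) <- list(c("a", "b"), c("a", "b"))
  expect_equal(decorrelate_bvs(bv, K), bv, ignore_attr = TRUE)

  K2 <- matrix(c(1, .5, .5, 1), 2, 2, dimnames = dimnames(K))
  out <- decorrelate_bvs(bv, K2)
  # L = [[1, 0], [.5, .8660]]; column (1,1) -> (1, 0.57735)
  expect_equal(unname(out[, "P"]), c(1, 0.5773503), tolerance = 1e-6)
  # re-correlating with L is the identity
  L <- t(chol(K2))
  expect_equal(unname(L %*% out), unname(bv), tolerance = 1e-12)

  sing <- matrix(1, 2, 2, dimnames = dimnames(K))
  expect_error(decorrelate_bvs(bv, sing), "positive definite")
})

test_that("decorrelated simulated BVs lose kinship but keep trait covariance", {
  cfg <- tiny_config(n_families = 80, offspring = 5,
                     Sigma_a = matrix(c(1, .6, .6, 1), 2), seed = 20)
  ped <- simulate_pedigree(cfg)
  study <- simulate_traits(ped, cfg)
  A <- build_A(ped)
  a <- study$true_direct_bvs
  astar <- decorrelate_bvs(a, A)
  # trait covariance approximately Sigma_a
  expect_equal(unname(crossprod(astar) / nrow(astar)),
               matrix(c(1, .6, .6, 1), 2), tolerance = 0.15)
  # half-sib cross-tree correlation is gone
  fam <- split(ped$id[!is.na(ped$dam)], ped$dam[!is.na(ped$dam)])
  fam <- fam[lengths(fam) >= 2]
  pairs <- do.call(rbind, lapply(fam, function(x) t(utils::combn(x, 2))))
  r_raw <- cor(a[pairs[, 1], 1], a[pairs[, 2], 1])
  r_dec <- cor(astar[pairs[, 1], 1], astar[pairs[, 2], 1])
  expect_gt(r_raw, 0.15)
  expect_lt(abs(r_dec), 3 * sqrt(1 / nrow(pairs)))
})

test_that("network scores decompose exactly and rank true structures", {
  X <- simulate_dag_data(500, c("A", "B", "C"),
                         data.frame(from = c("A", "B"), to = c("B", "C"),
                                    beta = c(0.8, 0.8)), seed = 21)
  chain <- dag_from_edges(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  emptyg <- empty_dag(c("A", "B", "C"))
  for (fn in list(bic_score, bge_score)) {
    s <- fn(X, chain)
    expect_equal(as.numeric(s), sum(attr(s, "local")), tolerance = 1e-9)
    expect_gt(as.numeric(s), as.numeric(fn(X, emptyg)))  # chain beats empty
  }
  # independent columns: empty graph beats any single-edge graph
  X0 <- simulate_dag_data(500, c("A", "B", "C"), seed = 22)
  one <- dag_from_edges(c("A", "B", "C"), "A", "B")
  expect_gt(as.numeric(bic_score(X0, emptyg)), as.numeric(bic_score(X0, one)))
  # adding a true strong edge increases the BIC score
  expect_gt(as.numeric(bic_score(X, dag_from_edges(c("A","B","C"), "A", "B"))),
            as.numeric(bic_score(X, emptyg)))
  expect_error(bic_score(matrix(rnorm(8), 2,
                                dimnames = list(NULL, c("A", "B", "C", "D"))),
                         dag_from_edges(c("A", "B", "C", "D"),
                                        c("A", "B", "C"), c("D", "D", "D"))),
               "more parents")
})

test_that("BGe is exactly score equivalent on Markov-equivalent DAGs", {
  X <- simulate_dag_data(200, c("X", "Y"), data.frame(from = "X", to = "Y",
                                                      beta = 0.5), seed = 23)
  s1 <- as.numeric(bge_score(X, dag_from_edges(c("X", "Y"), "X", "Y")))
  s2 <- as.numeric(bge_score(X, dag_from_edges(c("X", "Y"), "Y", "X")))
  expect_equal(s1, s2, tolerance = 1e-10)

  # all Markov-equivalent 3-node DAG pairs: chains and forks are equivalent,
  # the collider is not
  X3 <- simulate_dag_data(150, c("A", "B", "C"),
                          data.frame(from = c("A", "B"), to = c("B", "C"),
                                     beta = c(.5, .5)), seed = 24)
  chains <- list(dag_from_edges(c("A","B","C"), c("A","B"), c("B","C")),
                 dag_from_edges(c("A","B","C"), c("C","B"), c("B","A")),
                 dag_from_edges(c("A","B","C"), c("B","B"), c("A","C")))
  ss <- vapply(chains, function(d) as.numeric(bge_score(X3, d)), 0)
  expect_equal(max(ss) - min(ss), 0, tolerance = 1e-9)
  collider <- dag_from_edges(c("A","B","C"), c("A","C"), c("B","B"))
  expect_gt(abs(as.numeric(bge_score(X3, collider)) - ss[1]), 1e-6)
})

test_that("hill climbing finds the exhaustive optimum on 4-node problems", {
  nodes <- c("A", "B", "C", "D")
  all_dags <- enumerate_dags(nodes)
  expect_length(all_dags, 543)
  set.seed(25)
  for (rep in 1:4) {
    edges <- data.frame(from = c("A", "A", "C"), to = c("B", "C", "D"),
                        beta = runif(3, 0.3, 0.9))
    X <- simulate_dag_data(300, nodes, edges, seed = 100 + rep)
    best_exh <- max(vapply(all_dags, function(am) score_amat(X, am), 0))
    hc <- hill_climb(X, "bic")
    expect_equal(attr(hc, "score"), best_exh, tolerance = 1e-8)
  }
  # independent columns -> empty graph; determinism
  X0 <- simulate_dag_data(300, nodes, seed = 26)
  expect_equal(dag_n_edges(hill_climb(X0, "bic")), 0)
  expect_identical(hill_climb(X0, "bic", restarts = 2, seed = 7)$amat,
                   hill_climb(X0, "bic", restarts = 2, seed = 7)$amat)
})

test_that("tabu search never falls below the hill-climbing optimum", {
  nodes <- paste0("N", 1:6)
  set.seed(27)
  for (rep in 1:20) {
    k <- sample(3:7, 1)
    pairs <- t(utils::combn(6, 2))[sample(15, k), , drop = FALSE]
    edges <- data.frame(from = nodes[pairs[, 1]], to = nodes[pairs[, 2]],
                        beta = runif(k, -0.8, 0.8))
    X <- simulate_dag_data(150, nodes, edges, seed = 200 + rep)
    hc <- hill_climb(X, "bic")
    tb <- tabu_search(X, "bic", tabu_len = 10, max_iter = 30)
    expect_gte(attr(tb, "score"), attr(hc, "score") - 1e-9)
  }
  X0 <- simulate_dag_data(200, nodes, seed = 28)
  expect_equal(dag_n_edges(tabu_search(X0, "bic")), 0)
  expect_identical(tabu_search(X0, "bic", seed = 3)$amat,
                   tabu_search(X0, "bic", seed = 3)$amat)
})

test_that("bootstrap averaging scores edge strength and direction sensibly", {
  X <- simulate_dag_data(400, c("U", "V", "W"),
                         data.frame(from = c("U", "V"), to = c("V", "W"),
                                    beta = c(0.9, 0.9)), seed = 29)
  avg <- bootstrap_average(X, n_boot = 100, threshold = 0.95, seed = 30)
  uv <- avg$arcs[paste(avg$arcs$from, avg$arcs$to) %in% c("U V", "V U"), ]
  expect_gte(uv$strength, 0.99)
  expect_true(dag_n_edges(avg$consensus) >= 2)
  expect_false(is.null(avg$consensus$topo))  # consensus is acyclic

  # strengths invariant to row permutation of the data
  set.seed(31)
  avg2 <- bootstrap_average(X[sample(nrow(X)), ], n_boot = 100,
                            threshold = 0.95, seed = 30)
  strong1 <- avg$arcs[avg$arcs$strength >= 0.95, c("from", "to")]
  strong2 <- avg2$arcs[avg2$arcs$strength >= 0.95, c("from", "to")]
  expect_identical(strong1[order(strong1$from), ], strong2[order(strong2$from), ],
                   ignore_attr = TRUE)

  # collider orientation is identifiable: direction confidence > 0.5
  Xc <- simulate_dag_data(400, c("A", "B", "C"), data.frame(
    from = c("A", "C"), to = c("B", "B"), beta = c(0.8, 0.8)), seed = 32)
  avgc <- bootstrap_average(Xc, n_boot = 100, threshold = 0.5, seed = 33)
  ab <- avgc$arcs[avgc$arcs$from == "A" & avgc$arcs$to == "B", ]
  expect_equal(nrow(ab), 1)
  expect_gt(ab$direction, 0.5)
  expect_error(bootstrap_average(X, n_boot = 0), "n_boot")
})

test_that("arc removal deltas decompose and flag influential arcs", {
  X <- simulate_dag_data(400, c("A", "B", "C"),
                         data.frame(from = c("A", "B"), to = c("B", "C"),
                                    beta = c(0.9, 0.2)), seed = 34)
  dag <- dag_from_edges(c("A", "B", "C"), c("A", "B"), c("B", "C"))
  tab <- arc_removal_delta(X, dag, "bic")
  expect_equal(nrow(tab), 2)
  expect_true(all(diff(tab$delta) <= 0))      # sorted descending
  expect_equal(tab$from[1], "A")              # strong arc ranks first
  # decomposability: delta equals the full score difference
  d_full <- as.numeric(bic_score(X, dag))
  d_minus <- as.numeric(bic_score(X, dag_from_edges(c("A","B","C"), "B", "C")))
  expect_equal(tab$delta[tab$from == "A"], d_full - d_minus, tolerance = 1e-9)
  # removing a no-effect arc cannot raise the score much at large n
  X0 <- simulate_dag_data(800, c("A", "B"), seed = 35)
  d0 <- arc_removal_delta(X0, dag_from_edges(c("A", "B"), "A", "B"), "bic")
  expect_lt(d0$delta[1], 0)
})
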