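test_that("kNN selection on the toy drugs matches hand enumeration", {
  toy <- toy_fixture()
  raw <- build_knn_adjacency(toy$drug_sim, k = 1, symmetrize = FALSE)
  expect_equal(unname(raw),
               matrix(c(1, 1, 0,
                        1, 1, 0,
                        0, 1, 1), 3, 3, byrow = TRUE))
  sym <- build_knn_adjacency(toy$drug_sim, k = 1)
  expect_equal(sym[1, 2], 1)
  expect_equal(sym[2, 3], 1)  # union symmetrisation adds the reverse edge
  expect_equal(sym, t(sym))
})

test_that("ties are broken toward the smallest index", {
  A <- build_knn_adjacency(similarity_matrix(diag(3)), k = 1, symmetrize = FALSE)
  # all off-diagonal similarities tie at 0: row i picks the lowest other index
  expect_equal(unname(A),
               matrix(c(1, 1, 0,
                        1, 1, 0,
                        1, 0, 1), 3, 3, byrow = TRUE))
})

test_that("k = n - 1 yields the complete graph and k is range-checked", {
  toy <- toy_fixture()
  expect_equal(unname(build_knn_adjacency(toy$drug_sim, 2)), matrix(1, 3, 3))
  expect_error(build_knn_adjacency(toy$drug_sim, 0), "k must be")
  expect_error(build_knn_adjacency(toy$drug_sim, 3), "k must be")
})

test_that("kNN adjacency agrees with the brute-force oracle on random matrices", {
  for (seed in 1:4) {
    set.seed(seed)
    n <- sample(10:50, 1)
    S <- matrix(runif(n * n), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    for (k in c(1, 2, 4, 8)) {
      got <- build_knn_adjacency(S, k)
      expect_equal(got, oracle_knn(S, k),
                   info = sprintf("seed %d n %d k %d", seed, n, k))
    }
  }
})

test_that("self-loops are always present and edge sets nest as k grows", {
  set.seed(9)
  S <- matrix(runif(225), 15, 15)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  prev <- NULL
  for (k in 1:8) {
    A <- build_knn_adjacency(S, k)
    expect_equal(unname(diag(A)), rep(1, 15))
    if (!is.null(prev)) expect_true(all(A >= prev))
    prev <- A
  }
})

test_that("symmetric normalisation matches its definition", {
  expect_equal(normalize_adjacency(matrix(1, 1, 1)), matrix(1, 1, 1))
  expect_equal(normalize_adjacency(matrix(1, 2, 2)), matrix(0.5, 2, 2))

  set.seed(3)
  A <- oracle_knn(matrix(runif(100), 10, 10), 3)
  Nm <- normalize_adjacency(A)
  expect_equal(Nm, oracle_normalize(A), tolerance = 1e-12)
  expect_equal(Nm, t(Nm))

  expect_error(normalize_adjacency(matrix(0, 2, 2)), "zero-degree")
})

test_that("knn_graph bundles adjacency with its operator", {
  g <- knn_graph(toy_fixture()$drug_sim, 1)
  expect_s3_class(g, "drf_knn_graph")
  expect_equal(g$operator, normalize_adjacency(g$adjacency))
  el <- adjacency_edgelist(g$adjacency)
  expect_true(all(c("from", "to") %in% names(el)))
  expect_equal(nrow(el), sum(g$adjacency[upper.tri(g$adjacency, diag = TRUE)]))
})
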