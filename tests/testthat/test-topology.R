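test_that("edge typing on the toy graph follows the training mask", {
  toy <- toy_fixture()
  tg <- build_topology_graph(toy$assoc)
  expect_equal(sum(tg$a1), 3)           # type-1: the three known associations
  expect_equal(sum(1 - tg$a1), 3)       # type-0: the remaining pairs

  # masking pair (1,1) moves it from type 1 to type 0
  mask <- matrix(TRUE, 3, 2); mask[1, 1] <- FALSE
  tg2 <- build_topology_graph(toy$assoc, mask)
  expect_equal(sum(tg2$a1), 2)
  expect_equal(tg2$a1[1, 1], 0)

  # an all-ones association matrix leaves the type-0 channel empty: allowed
  tg3 <- build_topology_graph(association_matrix(matrix(1, 2, 2)))
  expect_equal(unname(tg3$deg0_r), c(0, 0))
  expect_equal(unname(tg3$s0d), c(0, 0))

  expect_error(build_topology_graph(toy$assoc, matrix(FALSE, 3, 2)),
               "degenerate")
})

test_that("one-round message passing reproduces the hand-computed case", {
  # one drug linked to both diseases (type 1), no type-0 edges anywhere;
  # disease identity features: h = tanh(sum_j x_j / sqrt(2 * 1))
  topo <- structure(list(n = 1, m = 2,
                         a1 = matrix(1, 1, 2),
                         m1 = matrix(1 / sqrt(2), 1, 2),
                         deg1_r = 2, deg1_d = c(1, 1),
                         deg0_r = 0, deg0_d = c(0, 0),
                         s0r = 0, s0d = c(0, 0)),
                    class = "drf_topology")
  tab0 <- matrix(0, 3, 2)
  tab1 <- rbind(c(0, 0), diag(2))   # drug row, then one-hot disease rows
  out <- message_passing_forward(topo, list(table = list(t0 = tab0, t1 = tab1)),
                                 n_rounds = 1)
  expect_equal(unname(out$drug), matrix(tanh(1 / sqrt(2)), 1, 2),
               tolerance = 1e-12)
})

test_that("all-zero tables give tanh(0) = 0 hidden states", {
  toy <- toy_fixture()
  tg <- build_topology_graph(toy$assoc)
  out <- message_passing_forward(tg, list(table = list(t0 = matrix(0, 5, 3),
                                                       t1 = matrix(0, 5, 3))),
                                 n_rounds = 1)
  expect_true(all(out$drug == 0) && all(out$disease == 0))
})

test_that("complement-identity type-0 channel matches the explicit double loop", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(4:20, 1); m <- sample(4:20, 1); h <- 3
    Y <- matrix(rbinom(n * m, 1, 0.3), n, m)
    if (sum(Y) == 0) Y[1, 1] <- 1
    tg <- build_topology_graph(association_matrix(Y))
    t0 <- matrix(rnorm((n + m) * h), n + m, h)
    t1 <- matrix(rnorm((n + m) * h), n + m, h)
    rw <- list(list(w0 = matrix(rnorm(h * h), h, h),
                    w1 = matrix(rnorm(h * h), h, h)))
    for (rounds in 1:2) {
      got <- message_passing_forward(tg, list(table = list(t0 = t0, t1 = t1),
                                              rounds = rw), n_rounds = rounds)
      want <- oracle_message_passing(Y, t0, t1, rw, n_rounds = rounds)
      expect_lt(max(abs(got$drug - want$drug)), 1e-8)
      expect_lt(max(abs(got$disease - want$disease)), 1e-8)
    }
  }
})

test_that("hidden states are tanh-bounded and deterministic", {
  set.seed(30)
  Y <- matrix(rbinom(60, 1, 0.4), 6, 10); Y[1, 1] <- 1
  tg <- build_topology_graph(association_matrix(Y))
  pars <- list(table = list(t0 = matrix(rnorm(64), 16, 4),
                            t1 = matrix(rnorm(64), 16, 4)),
               rounds = list(list(w0 = diag(4), w1 = diag(4))))
  a <- message_passing_forward(tg, pars, 2)
  b <- message_passing_forward(tg, pars, 2)
  expect_identical(a, b)
  expect_true(all(abs(a$drug) < 1) && all(abs(a$disease) < 1))
})

test_that("the dense output transform is plain matrix multiplication", {
  h <- matrix(rnorm(12), 4, 3)
  expect_equal(dense_transform(h, diag(3)), h)
  expect_equal(dense_transform(h, matrix(0, 3, 3)), matrix(0, 4, 3))
  set.seed(8)
  w <- matrix(rnorm(9), 3, 3)
  expect_equal(dense_transform(h, w), h %*% w, tolerance = 1e-12)
  expect_error(dense_transform(h, diag(4)), "mismatch")
})
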