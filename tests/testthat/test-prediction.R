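make_mlp <- function(h, h1, h2, seed = 1, zero = FALSE) {
  if (zero) return(list(W1 = matrix(0, 2 * h, h1), b1 = numeric(h1),
                        W2 = matrix(0, h1, h2), b2 = numeric(h2),
                        w3 = numeric(h2), b3 = 0))
  set.seed(seed)
  list(W1 = matrix(rnorm(2 * h * h1, sd = 0.5), 2 * h, h1), b1 = rnorm(h1),
       W2 = matrix(rnorm(h1 * h2, sd = 0.5), h1, h2), b2 = rnorm(h2),
       w3 = rnorm(h2), b3 = rnorm(1))
}

test_that("the pair MLP matches a layer-by-layer oracle and its edge cases", {
  set.seed(40)
  zr <- matrix(rnorm(12), 3, 4)
  zd <- matrix(rnorm(8), 2, 4)
  pairs <- as.matrix(expand.grid(1:3, 1:2))

  # all-zero parameters: sigmoid(0) = 0.5 for every pair
  s0 <- predict_pairs(zr, zd, make_mlp(4, 3, 2, zero = TRUE), pairs)
  expect_equal(as.numeric(s0), rep(0.5, 6))

  mlp <- make_mlp(4, 3, 2, seed = 41)
  s <- predict_pairs(zr, zd, mlp, pairs)
  want <- apply(pairs, 1, function(p) oracle_mlp_pair(zr[p[1], ], zd[p[2], ], mlp))
  expect_lt(max(abs(as.numeric(s) - want)), 1e-10)

  # identical drug embeddings give identical score rows
  zr2 <- zr; zr2[2, ] <- zr2[1, ]
  s2 <- predict_pairs(zr2, zd, mlp, pairs)
  expect_equal(s2[pairs[, 1] == 1], s2[pairs[, 1] == 2])

  expect_error(predict_pairs(zr, zd[, 1:3], mlp, pairs), "width")
})

test_that("binary cross-entropy matches closed forms", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), -log(0.9) - log(0.8),
               tolerance = 1e-12)
  # near-perfect predictions drive the loss to zero
  expect_lt(bce_loss(c(1 - 1e-13, 1e-13), c(1, 0)), 1e-10)
  # clamped logs keep catastrophic predictions finite
  expect_true(is.finite(bce_loss(c(1e-20), c(1))))
  expect_error(bce_loss(numeric(0), numeric(0)), "empty")
})

test_that("embedding similarity is the row-cosine matrix", {
  expect_equal(embedding_similarity(diag(3)), diag(3))

  z <- rbind(c(1, 0), c(2, 0), c(0, 3))
  s <- embedding_similarity(z)
  expect_equal(s[1, 2], 1)     # duplicated direction
  expect_equal(s[1, 3], 0)

  set.seed(50)
  z <- matrix(rnorm(12), 4, 3)
  expect_lt(max(abs(embedding_similarity(z) - oracle_cosine(z))), 1e-12)

  expect_error(embedding_similarity(rbind(c(0, 0), c(1, 1))), "zero")
})

test_that("cosine structure is invariant to shared orthogonal rotation", {
  set.seed(51)
  z <- matrix(rnorm(20), 5, 4)
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_lt(max(abs(embedding_similarity(z %*% q) - embedding_similarity(z))),
            1e-10)
})

test_that("consistency penalty is the squared Frobenius distance", {
  s <- matrix(runif(9), 3, 3)
  expect_equal(consistency_loss(s, s), 0)
  expect_equal(consistency_loss(matrix(0.5, 2, 2), matrix(0, 2, 2)), 1)
  set.seed(52)
  a <- matrix(rnorm(16), 4, 4); b <- matrix(rnorm(16), 4, 4)
  expect_gte(consistency_loss(a, b), 0)
  expect_equal(consistency_loss(a, b), sum((a - b)^2), tolerance = 1e-12)
})

test_that("the total objective combines its three terms exactly", {
  expect_equal(total_loss(1, 2, 3, 0.1)$l_total, 1.5)
  expect_equal(total_loss(7, 100, 100, 0)$l_total, 7)
  tl <- total_loss(2, 3, 4, 0.5)
  expect_identical(tl$l_total, tl$l_bce + tl$lambda * (tl$l_cr + tl$l_cd))
})
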