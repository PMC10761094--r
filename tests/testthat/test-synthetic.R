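test_that("the generator is fully determined by its seed", {
  sp <- synth_spec(n_drugs = 30, n_diseases = 20, latent_rank = 3, seed = 11)
  d1 <- generate_planted_dataset(sp)
  d2 <- generate_planted_dataset(sp)
  expect_identical(unclass(d1$assoc), unclass(d2$assoc))
  expect_identical(unclass(d1$drug_sim), unclass(d2$drug_sim))
  expect_identical(d1$truth, d2$truth)

  d3 <- generate_planted_dataset(synth_spec(n_drugs = 30, n_diseases = 20,
                                            latent_rank = 3, seed = 12))
  expect_false(identical(unclass(d1$assoc), unclass(d3$assoc)))
})

test_that("generated similarity matrices pass validation for a range of specs", {
  for (noise in c(0, 0.05, 0.5)) {
    d <- generate_planted_dataset(synth_spec(n_drugs = 25, n_diseases = 15,
                                             latent_rank = 2,
                                             similarity_noise = noise,
                                             seed = 5))
    expect_s3_class(d$drug_sim, "drf_similarity")
    expect_s3_class(d$disease_sim, "drf_similarity")
    expect_true(all(unclass(d$drug_sim) >= 0 & unclass(d$drug_sim) <= 1))
    expect_equal(unname(diag(unclass(d$disease_sim))), rep(1, 15))
  }
})

test_that("noise-free similarity equals rescaled cosine of the latent factors", {
  sp <- synth_spec(n_drugs = 12, n_diseases = 8, latent_rank = 3,
                   similarity_noise = 0, seed = 21)
  d <- generate_planted_dataset(sp)
  set.seed(sp$seed)
  U <- matrix(rnorm(12 * 3), 12, 3)
  cos_u <- oracle_cosine(U)
  expected <- (1 + cos_u) / 2
  diag(expected) <- 1
  expect_equal(bare(d$drug_sim), expected, tolerance = 1e-12)
  # identical latent rows would give cosine 1, the diagonal case
  expect_equal(unname(diag(unclass(d$drug_sim))), rep(1, 12))
})

test_that("realized density concentrates near the target", {
  d <- generate_planted_dataset(synth_spec(n_drugs = 100, n_diseases = 80,
                                           latent_rank = 4, density = 0.05,
                                           seed = 7))
  realized <- dataset_summary(d$assoc)$sparsity
  expect_lt(abs(realized - 0.05), 0.02)
  # truth propensities hit the target even closer (bisection tolerance 1e-3)
  expect_lt(abs(mean(d$truth) - 0.05), 2e-3)
})

test_that("invalid specs are rejected", {
  expect_error(synth_spec(n_drugs = 3, n_diseases = 5, latent_rank = 4))
  expect_error(synth_spec(density = 0))
  expect_error(synth_spec(density = 1))
})

test_that("the toy fixture has its documented shape", {
  toy <- toy_fixture()
  s <- dataset_summary(toy$assoc)
  expect_equal(s$n_associations, 3)
  expect_equal(s$sparsity, 0.5)
  # drug 3 (index 3) is the cold-start probe: no known indications
  expect_equal(unname(rowSums(unclass(toy$assoc))), c(1, 2, 0))
  expect_equal(dim(unclass(toy$drug_sim)), c(3L, 3L))
  expect_equal(dim(unclass(toy$disease_sim)), c(2L, 2L))
})
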