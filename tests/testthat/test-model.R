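tiny_config <- function(epochs = 120, seed = 1, ...) {
  model_config(epochs = epochs, k = 1, hidden = 8, attention_hidden = 4,
               seed = seed, ...)
}

test_that("training reduces the BCE loss on the toy dataset", {
  fit <- train_model(toy_fixture(), tiny_config(dropout = 0))
  expect_lt(utils::tail(fit$history$l_bce, 1), fit$history$l_bce[1])
  # the deterministic run should fit three-positive toy labels well
  expect_lt(utils::tail(fit$history$l_bce, 1), 1)
})

test_that("a fixed seed reproduces training exactly, dropout included", {
  cfg <- tiny_config(epochs = 60, dropout = 0.3)
  f1 <- train_model(toy_fixture(), cfg)
  f2 <- train_model(toy_fixture(), cfg)
  expect_equal(utils::tail(f1$history$l_total, 1),
               utils::tail(f2$history$l_total, 1), tolerance = 1e-10)
  expect_equal(f1$params$mlp$w3, f2$params$mlp$w3, tolerance = 1e-12)
  expect_equal(predict(f1), predict(f2), tolerance = 1e-12)

  f3 <- train_model(toy_fixture(), tiny_config(epochs = 60, dropout = 0.3,
                                               seed = 2))
  expect_false(isTRUE(all.equal(predict(f1), predict(f3))))
})

test_that("the model has the capacity to overfit a small planted dataset", {
  d <- generate_planted_dataset(synth_spec(n_drugs = 40, n_diseases = 30,
                                           latent_rank = 2, density = 0.1,
                                           similarity_noise = 0.05, seed = 5))
  cfg <- model_config(epochs = 700, hidden = 16, attention_hidden = 8, seed = 2)
  fit <- train_model(d, cfg)
  train_pairs <- which(matrix(TRUE, 40, 30), arr.ind = TRUE)
  res <- evaluate(predict(fit), unclass(d$assoc), train_pairs)
  expect_gte(res$auroc, 0.95)
})

test_that("disabling attention freezes fusion at the midpoint", {
  fit <- train_model(toy_fixture(), tiny_config(epochs = 40, ablation = "w/o-a"))
  expect_null(fit$attention)
  expect_equal(fit$embeddings$z_r,
               (fit$embeddings$z_fr + fit$embeddings$z_tr) / 2,
               tolerance = 1e-12)
})

test_that("removing one space routes its partner straight to the predictor", {
  ff <- train_model(toy_fixture(), tiny_config(epochs = 40, ablation = "w/o-t"))
  expect_identical(ff$embeddings$z_r, ff$embeddings$z_fr)
  expect_false("z_tr" %in% names(ff$embeddings))

  ft <- train_model(toy_fixture(), tiny_config(epochs = 40, ablation = "w/o-f"))
  expect_identical(ft$embeddings$z_r, ft$embeddings$z_tr)
  expect_false("z_fr" %in% names(ft$embeddings))
})

test_that("lambda = 0 and the no-consistency ablation coincide exactly", {
  f0 <- train_model(toy_fixture(), tiny_config(epochs = 50, lambda = 0))
  fl <- train_model(toy_fixture(), tiny_config(epochs = 50, ablation = "w/o-l"))
  expect_equal(f0$history$l_total, fl$history$l_total, tolerance = 1e-12)
  expect_equal(predict(f0), predict(fl), tolerance = 1e-12)
})

test_that("prediction outputs respect container conventions", {
  toy <- toy_fixture()
  fit <- train_model(toy, tiny_config(epochs = 40))
  scores <- predict(fit)
  expect_equal(dim(scores), c(3L, 2L))
  expect_true(all(scores > 0 & scores < 1))
  expect_identical(rownames(scores), c("d0", "d1", "d2"))

  tb <- predict(fit, pairs = cbind(c(1, 3), c(2, 1)))
  expect_equal(nrow(tb), 2)
  expect_identical(tb$drug, c("d0", "d2"))

  cand <- rank_candidates(fit, toy$assoc)
  expect_equal(nrow(cand), 3)  # the three unknown pairs
  expect_true(all(diff(cand$score) <= 0))
  known <- with(cand, paste(drug, disease)) %in% c("d0 s0", "d1 s0", "d1 s1")
  expect_false(any(known))
})

test_that("tidy and glance expose attention and configuration summaries", {
  fit <- train_model(toy_fixture(), tiny_config(epochs = 40))
  td <- tidy(fit)
  expect_equal(nrow(td), 5)  # 3 drugs + 2 diseases
  expect_equal(td$alpha_feature + td$alpha_topology, rep(1, 5),
               tolerance = 1e-12)
  gl <- glance(fit)
  expect_equal(gl$epochs, 40L)
  expect_equal(gl$n_drugs, 3L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})

test_that("degenerate training inputs are rejected", {
  toy <- toy_fixture()
  expect_error(train_model(toy, tiny_config(), matrix(FALSE, 3, 2)), "empty")
  all_pos <- list(drug_sim = toy$drug_sim, disease_sim = toy$disease_sim,
                  assoc = association_matrix(matrix(1, 3, 2)))
  expect_error(train_model(all_pos, tiny_config()), "both labels")
})
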