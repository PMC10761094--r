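# Planted low-rank generator. Drug factors U (n x r) and disease factors
# V (m x r) are iid standard normal; the true association propensity is
# s_ij = sigmoid(U_i . V_j - theta) with theta tuned by bisection so that
# mean(s) hits the target density; labels are Bernoulli(s). Both similarity
# matrices are noisy functions of the same latent factors: unit-interval
# rescaled cosine similarity (1 + cos) / 2 plus symmetric Gaussian noise,
# clipped to [0, 1], diagonal forced to 1. One seed streams through all draws
# in a fixed order: U, V, labels, drug noise, disease noise.

#' Specification for a planted synthetic dataset
#'
#' @param n_drugs,n_diseases matrix dimensions.
#' @param latent_rank rank of the planted factor model (must not exceed the
#'   smaller dimension).
#' @param density target fraction of positive pairs, in (0, 1).
#' @param similarity_noise standard deviation of the symmetric Gaussian
#'   perturbation added to both similarity matrices.
#' @param seed integer seed; fully determines the generated dataset.
#' @return a `drf_synth_spec` list.
#' @export
synth_spec <- function(n_drugs = 100, n_diseases = 80, latent_rank = 4,
                       density = 0.05, similarity_noise = 0.1, seed = 1) {
  stopifnot(n_drugs >= 1, n_diseases >= 1,
            latent_rank >= 1, latent_rank <= min(n_drugs, n_diseases),
            density > 0, density < 1, similarity_noise >= 0)
  structure(list(n_drugs = n_drugs, n_diseases = n_diseases,
                 latent_rank = latent_rank, density = density,
                 similarity_noise = similarity_noise, seed = as.integer(seed)),
            class = "drf_synth_spec")
}

cosine_rows <- function(X) {
  nrm <- sqrt(rowSums(X^2))
  nrm[nrm == 0] <- 1
  Xn <- X / nrm
  tcrossprod(Xn)
}

# theta such that mean(sigmoid(G - theta)) ~= density, by bisection.
solve_threshold <- function(G, density, tol = 1e-3, max_iter = 200) {
  f <- function(theta) mean(stats::plogis(G - theta)) - density
  lo <- min(G) - 20
  hi <- max(G) + 20
  if (f(lo) < 0 || f(hi) > 0)
    stop("density target infeasible for the drawn factors", call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v) < tol) return(mid)
    if (v > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

noisy_unit_similarity <- function(factors, noise, kind) {
  S <- (1 + cosine_rows(factors)) / 2
  n <- nrow(S)
  if (noise > 0) {
    E <- matrix(stats::rnorm(n * n, sd = noise), n, n)
    S <- S + (E + t(E)) / 2
  }
  S <- pmin(pmax(S, 0), 1)
  diag(S) <- 1
  similarity_matrix(S, entity_kind = kind)
}

#' Generate a planted low-rank drug-disease dataset
#'
#' Emulates the benchmark layout (binary association matrix plus drug and
#' disease similarity matrices) with known ground truth: the returned
#' `truth` matrix holds the Bernoulli propensities every label was drawn
#' from, usable as an evaluation oracle.
#'
#' @param spec a [synth_spec()].
#' @return list with `drug_sim`, `disease_sim`, `assoc`, `truth` (n x m
#'   propensity matrix) and `spec`.
#' @export
#' @examples
#' d <- generate_planted_dataset(synth_spec(n_drugs = 20, n_diseases = 15,
#'                                          latent_rank = 2, seed = 3))
#' dataset_summary(d$assoc)
generate_planted_dataset <- function(spec) {
  stopifnot(inherits(spec, "drf_synth_spec"))
  n <- spec$n_drugs; m <- spec$n_diseases; r <- spec$latent_rank
  set.seed(spec$seed)
  U <- matrix(stats::rnorm(n * r), n, r)
  V <- matrix(stats::rnorm(m * r), m, r)
  G <- tcrossprod(U, V)
  theta <- solve_threshold(G, spec$density)
  truth <- stats::plogis(G - theta)
  Y <- matrix(stats::rbinom(n * m, 1, as.vector(truth)), n, m)
  drug_sim <- noisy_unit_similarity(U, spec$similarity_noise, "drug")
  disease_sim <- noisy_unit_similarity(V, spec$similarity_noise, "disease")
  assoc <- association_matrix(Y)
  dimnames(truth) <- dimnames(assoc)
  list(drug_sim = drug_sim, disease_sim = disease_sim, assoc = assoc,
       truth = truth, spec = spec)
}

#' Fixed miniature dataset used throughout the tests
#'
#' Three drugs, two diseases. Drugs 1 and 2 are highly similar (0.9) and both
#' treat disease 1; drug 3 is dissimilar from both and has no known
#' indication, which makes it the cold-start probe.
#'
#' @return list with `drug_sim` (3x3), `disease_sim` (2x2), `assoc` (3x2).
#' @export
toy_fixture <- function() {
  list(
    drug_sim = similarity_matrix(matrix(c(1, .9, .1,
                                          .9, 1, .2,
                                          .1, .2, 1), 3, 3, byrow = TRUE),
                                 entity_kind = "drug"),
    disease_sim = similarity_matrix(matrix(c(1, .3,
                                             .3, 1), 2, 2, byrow = TRUE),
                                    entity_kind = "disease"),
    assoc = association_matrix(matrix(c(1, 0,
                                        1, 1,
                                        0, 0), 3, 2, byrow = TRUE))
  )
}
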