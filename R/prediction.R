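# Pair scoring and the three-term training objective: a three-layer MLP on
# the concatenated fused embeddings gives sigmoid scores; binary
# cross-entropy (summed over training pairs) is regularised by consistency
# penalties that pull the cosine-similarity structures of the two spaces'
# embeddings together.

#' Score drug-disease pairs with the prediction MLP
#'
#' Each pair's fused drug and disease embeddings are concatenated and passed
#' through a three-layer MLP (two ReLU hidden layers and a scalar sigmoid
#' output).
#'
#' @param z_r fused drug embeddings (n x h).
#' @param z_d fused disease embeddings (m x h).
#' @param mlp list `W1, b1, W2, b2, w3, b3`.
#' @param pairs two-column integer matrix of (drug, disease) indices.
#' @param training,dropout dropout on the hidden layers during training.
#' @param keep_cache retain activations for backpropagation.
#' @return numeric score vector in (0, 1), one entry per pair.
#' @export
predict_pairs <- function(z_r, z_d, mlp, pairs, training = FALSE,
                          dropout = 0, keep_cache = FALSE) {
  stopifnot(ncol(pairs) == 2)
  x1 <- cbind(z_r[pairs[, 1], , drop = FALSE], z_d[pairs[, 2], , drop = FALSE])
  if (ncol(x1) != nrow(mlp$W1)) stop("MLP input width mismatch", call. = FALSE)
  pre1 <- x1 %*% mlp$W1
  pre1 <- pre1 + rep(mlp$b1, each = nrow(pre1))
  a1 <- relu(pre1)
  mask1 <- if (training) dropout_mask(nrow(a1), ncol(a1), dropout) else NULL
  a1d <- apply_mask(a1, mask1)
  pre2 <- a1d %*% mlp$W2
  pre2 <- pre2 + rep(mlp$b2, each = nrow(pre2))
  a2 <- relu(pre2)
  mask2 <- if (training) dropout_mask(nrow(a2), ncol(a2), dropout) else NULL
  a2d <- apply_mask(a2, mask2)
  logits <- drop(a2d %*% mlp$w3) + mlp$b3
  scores <- stats::plogis(logits)
  if (keep_cache)
    attr(scores, "cache") <- list(x1 = x1, pre1 = pre1, a1d = a1d,
                                  pre2 = pre2, a2d = a2d,
                                  mask1 = mask1, mask2 = mask2)
  scores
}

# Backward through the MLP given dL/dlogits; returns parameter grads and the
# gradient wrt the concatenated input (split by the caller).
mlp_backward <- function(mlp, cache, d_logits) {
  g_w3 <- drop(crossprod(cache$a2d, d_logits))
  g_b3 <- sum(d_logits)
  d_a2d <- outer(d_logits, mlp$w3)
  d_pre2 <- apply_mask(d_a2d, cache$mask2) * (cache$pre2 > 0)
  g_W2 <- crossprod(cache$a1d, d_pre2)
  g_b2 <- colSums(d_pre2)
  d_a1d <- d_pre2 %*% t(mlp$W2)
  d_pre1 <- apply_mask(d_a1d, cache$mask1) * (cache$pre1 > 0)
  g_W1 <- crossprod(cache$x1, d_pre1)
  g_b1 <- colSums(d_pre1)
  d_x1 <- d_pre1 %*% t(mlp$W1)
  list(pars = list(W1 = g_W1, b1 = g_b1, W2 = g_W2, b2 = g_b2,
                   w3 = g_w3, b3 = g_b3),
       x1 = d_x1)
}

#' Binary cross-entropy over a pair set
#'
#' Summed (not averaged) over pairs:
#' `L = -sum(y log yhat + (1 - y) log(1 - yhat))`, with logs clamped at
#' 1e-12 for numerical safety.
#'
#' @param scores predicted scores in (0, 1).
#' @param labels 0/1 labels of the same length.
#' @return nonnegative scalar.
#' @export
bce_loss <- function(scores, labels) {
  if (length(scores) == 0) stop("empty pair set in BCE loss", call. = FALSE)
  stopifnot(length(scores) == length(labels))
  -sum(labels * log(pmax(scores, 1e-12)) +
       (1 - labels) * log(pmax(1 - scores, 1e-12)))
}

#' Cosine-similarity structure of an embedding matrix
#'
#' Rows are L2-normalised, then `S = Z_norm Z_norm'`.
#'
#' @param z embedding matrix without zero rows.
#' @return square symmetric matrix with unit diagonal.
#' @export
embedding_similarity <- function(z) {
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm == 0))
    stop("zero embedding row: cosine similarity undefined", call. = FALSE)
  tcrossprod(z / nrm)
}

#' Consistency penalty between two similarity structures
#'
#' Squared Frobenius norm of the difference, `||S_F - S_T||_F^2`.
#'
#' @param s_f,s_t square matrices of identical shape.
#' @return nonnegative scalar.
#' @export
consistency_loss <- function(s_f, s_t) {
  stopifnot(identical(dim(s_f), dim(s_t)))
  sum((s_f - s_t)^2)
}

#' Assemble the three-term training objective
#'
#' `L = L_bce + lambda * L_Cr + lambda * L_Cd`, returned as a one-row tibble
#' breakdown.
#'
#' @param l_bce,l_cr,l_cd the three loss components.
#' @param lambda nonnegative trade-off weight.
#' @return tibble with columns `l_bce`, `l_cr`, `l_cd`, `lambda`, `l_total`.
#' @export
total_loss <- function(l_bce, l_cr = 0, l_cd = 0, lambda = 0) {
  stopifnot(lambda >= 0)
  tibble::tibble(l_bce = l_bce, l_cr = l_cr, l_cd = l_cd, lambda = lambda,
                 l_total = l_bce + lambda * l_cr + lambda * l_cd)
}

# Consistency gradient helper: returns dL/dZ_F and dL/dZ_T for one entity
# kind (L = ||S_F - S_T||_F^2 with S built from row-normalised embeddings).
# Row norms are floored at 1e-8: a ReLU can zero out an entire embedding row
# during training, and the cosine of a zero row is taken as zero rather than
# aborting the run (the strict embedding_similarity() keeps its hard error).
consistency_backward <- function(z_f, z_t) {
  norm_rows <- function(z) {
    r <- pmax(sqrt(rowSums(z^2)), 1e-8)
    list(n = z / r, r = r)
  }
  nf <- norm_rows(z_f); nt <- norm_rows(z_t)
  delta <- tcrossprod(nf$n) - tcrossprod(nt$n)
  d_nf <- 4 * delta %*% nf$n
  d_nt <- -4 * delta %*% nt$n
  unnorm <- function(dn, nn) (dn - nn$n * rowSums(nn$n * dn)) / nn$r
  list(loss = sum(delta^2),
       z_f = unnorm(d_nf, nf),
       z_t = unnorm(d_nt, nt))
}
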