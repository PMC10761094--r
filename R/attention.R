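# Per-node attention over the two embedding spaces. Each node's embedding in
# each space is pushed through a space-specific affine map and tanh, scored
# against a shared attention vector, and the two scores are softmaxed into a
# convex pair of fusion weights.

#' Attention scores of one embedding space
#'
#' Computes `omega_i = q' tanh(W z_i' + b)` for every node (row of `z`).
#'
#' @param z embedding matrix (nodes x h).
#' @param w transform weight (h' x h).
#' @param b bias vector (length h').
#' @param q shared attention vector (length h').
#' @param keep_cache retain the tanh activations for backpropagation.
#' @return numeric score vector, one entry per node.
#' @export
attention_scores <- function(z, w, b, q, keep_cache = FALSE) {
  if (ncol(z) != ncol(w) || length(b) != nrow(w) || length(q) != nrow(w))
    stop("attention parameter shapes inconsistent with embeddings", call. = FALSE)
  act <- tanh(tcrossprod(z, w) + matrix(b, nrow(z), length(b), byrow = TRUE))
  s <- drop(act %*% q)
  if (keep_cache) attr(s, "cache") <- act
  s
}

#' Two-way softmax of feature/topology attention scores
#'
#' Normalises the per-node score pair to convex weights
#' `alpha_F = exp(wF) / (exp(wF) + exp(wT))`, computed stably as
#' `plogis(wF - wT)` so extreme scores cannot overflow.
#'
#' @param omega_f,omega_t equal-length score vectors.
#' @return list with `alpha_f` and `alpha_t` (`alpha_f + alpha_t = 1`).
#' @export
softmax_pair <- function(omega_f, omega_t) {
  stopifnot(length(omega_f) == length(omega_t))
  af <- stats::plogis(omega_f - omega_t)
  list(alpha_f = af, alpha_t = 1 - af)
}

#' Fuse the two spaces' embeddings with per-node weights
#'
#' Row `i` of the result is `alpha_f[i] * z_f[i, ] + alpha_t[i] * z_t[i, ]`.
#'
#' @param weights list with `alpha_f`, `alpha_t` (from [softmax_pair()]).
#' @param z_f,z_t embedding matrices of identical shape.
#' @return fused embedding matrix.
#' @export
fuse_embeddings <- function(weights, z_f, z_t) {
  stopifnot(identical(dim(z_f), dim(z_t)),
            length(weights$alpha_f) == nrow(z_f))
  z_f * weights$alpha_f + z_t * weights$alpha_t
}

# Full attention block for one entity kind; returns fused embedding + cache.
attention_forward <- function(z_f, z_t, pars, keep_cache = FALSE) {
  sF <- attention_scores(z_f, pars$WF, pars$bF, pars$q, keep_cache = keep_cache)
  sT <- attention_scores(z_t, pars$WT, pars$bT, pars$q, keep_cache = keep_cache)
  w <- softmax_pair(as.numeric(sF), as.numeric(sT))
  fused <- fuse_embeddings(w, z_f, z_t)
  if (!keep_cache) return(list(fused = fused, weights = w))
  list(fused = fused, weights = w,
       cache = list(cF = attr(sF, "cache"), cT = attr(sT, "cache")))
}

# Backward through the attention block. grad is dL/d(fused). Returns
# parameter gradients plus dL/dz_f, dL/dz_t.
attention_backward <- function(z_f, z_t, pars, fwd, grad) {
  af <- fwd$weights$alpha_f; at <- fwd$weights$alpha_t
  cF <- fwd$cache$cF; cT <- fwd$cache$cT
  d_alpha <- rowSums(grad * (z_f - z_t))
  g_zf <- grad * af
  g_zt <- grad * at
  delta <- d_alpha * af * at           # d alpha_f / d (wF - wT)
  d_sF <- delta; d_sT <- -delta
  g_q <- drop(crossprod(cF, d_sF) + crossprod(cT, d_sT))
  dPF <- outer(d_sF, pars$q) * (1 - cF^2)
  dPT <- outer(d_sT, pars$q) * (1 - cT^2)
  g_WF <- crossprod(dPF, z_f); g_bF <- colSums(dPF)
  g_WT <- crossprod(dPT, z_t); g_bT <- colSums(dPT)
  g_zf <- g_zf + dPF %*% pars$WF
  g_zt <- g_zt + dPT %*% pars$WT
  list(pars = list(WF = g_WF, bF = g_bF, WT = g_WT, bT = g_bT, q = g_q),
       z_f = g_zf, z_t = g_zt)
}
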