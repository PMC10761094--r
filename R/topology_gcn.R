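# Topology-space propagation over the bipartite association graph, in the
# matrix-completion style: separate message channels for edge type 1 (known,
# training-visible associations) and edge type 0 (every other drug-disease
# pair), symmetric normalisation 1/sqrt(|N_t(r_i)| |N_t(d_j)|), sum
# accumulation across types, tanh nonlinearity, and a final linear transform
# shared between drug and disease nodes.
#
# The type-0 channel is dense (almost every pair), so its matrix product is
# computed by the complement identity
#   M0 X = D0r^{-1/2} [ 1 (s0d' X) - A1 (s0d * X) ],   s0d = 1/sqrt(deg0_d),
# i.e. the total sum minus the type-1 contributions, never materialising the
# dense complement adjacency. Tests verify this against an explicit loop.

#' Build the typed bipartite topology graph
#'
#' Type-1 edges are the association-matrix positives visible through
#' `train_mask`; type-0 edges are all remaining drug-disease pairs (held-out
#' pairs are unknown at training time and therefore type 0). Neighbour counts
#' are per type.
#'
#' @param assoc binary association matrix (n drugs x m diseases).
#' @param train_mask logical n x m matrix; `TRUE` marks pairs whose label is
#'   visible during training. Default: all pairs.
#' @return a `drf_topology` list: `a1` (binary type-1 adjacency), normalised
#'   type-1 operator `m1`, per-type degree vectors, and the scaling vectors
#'   `s0r`, `s0d` of the complement channel.
#' @export
build_topology_graph <- function(assoc, train_mask = NULL) {
  Y <- unclass(assoc)
  n <- nrow(Y); m <- ncol(Y)
  if (is.null(train_mask)) train_mask <- matrix(TRUE, n, m)
  stopifnot(identical(dim(train_mask), c(n, m)))
  a1 <- Y * train_mask
  if (sum(a1) == 0)
    stop("no training-visible associations: topology graph is degenerate",
         call. = FALSE)
  deg1_r <- rowSums(a1); deg1_d <- colSums(a1)
  deg0_r <- m - deg1_r;  deg0_d <- n - deg1_d
  inv <- function(d) ifelse(d > 0, 1 / sqrt(d), 0)
  m1 <- a1 * outer(inv(deg1_r), inv(deg1_d))
  structure(list(n = n, m = m, a1 = a1, m1 = m1,
                 deg1_r = deg1_r, deg1_d = deg1_d,
                 deg0_r = deg0_r, deg0_d = deg0_d,
                 s0r = inv(deg0_r), s0d = inv(deg0_d)),
            class = "drf_topology")
}

# M0 %*% X (X: m x h) via the complement identity.
m0_mult <- function(topo, X) {
  Xs <- X * topo$s0d
  tot <- colSums(Xs)
  out <- matrix(tot, topo$n, length(tot), byrow = TRUE) - topo$a1 %*% Xs
  out * topo$s0r
}

# t(M0) %*% X (X: n x h).
m0_tmult <- function(topo, X) {
  Xs <- X * topo$s0r
  tot <- colSums(Xs)
  out <- matrix(tot, topo$m, length(tot), byrow = TRUE) - crossprod(topo$a1, Xs)
  out * topo$s0d
}

#' Edge-type message passing over the bipartite graph
#'
#' Round 1 embeds the one-hot node identities through the per-type embedding
#' tables (rows `1..n` are drugs, `n+1..n+m` diseases); each further round
#' transforms the opposite side's hidden states with per-type weight
#' matrices. Every round accumulates the two channels' normalised messages
#' and applies `tanh`. Dropout hits the hidden states between rounds during
#' training.
#'
#' @param topo a [build_topology_graph()] result.
#' @param params list with `table = list(t0, t1)` (the `(n+m) x h` per-type
#'   embedding tables) and, for rounds beyond the first,
#'   `rounds = list(list(w0, w1), ...)`.
#' @param n_rounds number of message-passing rounds.
#' @param training,dropout dropout control as in [feature_gcn_forward()].
#' @param keep_cache return intermediates for backpropagation.
#' @return list `(drug = H_r, disease = H_d)` of hidden-state matrices, with
#'   attribute `"cache"` when requested.
#' @export
message_passing_forward <- function(topo, params, n_rounds = 2,
                                    training = FALSE, dropout = 0,
                                    keep_cache = FALSE) {
  n <- topo$n; m <- topo$m
  t0 <- params$table$t0; t1 <- params$table$t1
  stopifnot(nrow(t0) == n + m, nrow(t1) == n + m)
  # round-1 message dropout: the embedding-table messages are the raw label
  # signal, and regularising them is what stops the label channel from
  # memorising the training positives (matrix-completion lineage)
  mask_t0 <- if (training) dropout_mask(n + m, ncol(t0), dropout) else NULL
  mask_t1 <- if (training) dropout_mask(n + m, ncol(t1), dropout) else NULL
  t0d <- apply_mask(t0, mask_t0)
  t1d <- apply_mask(t1, mask_t1)
  hr <- tanh(topo$m1 %*% t1d[n + seq_len(m), , drop = FALSE] +
             m0_mult(topo, t0d[n + seq_len(m), , drop = FALSE]))
  hd <- tanh(crossprod(topo$m1, t1d[seq_len(n), , drop = FALSE]) +
             m0_tmult(topo, t0d[seq_len(n), , drop = FALSE]))
  cache <- list(hr = list(hr), hd = list(hd),
                mask_r = list(), mask_d = list(),
                in_r = list(), in_d = list(),
                mask_t0 = mask_t0, mask_t1 = mask_t1)
  if (n_rounds > 1) {
    for (r in seq_len(n_rounds - 1)) {
      w0 <- params$rounds[[r]]$w0; w1 <- params$rounds[[r]]$w1
      mask_r <- if (training) dropout_mask(n, ncol(hr), dropout) else NULL
      mask_d <- if (training) dropout_mask(m, ncol(hd), dropout) else NULL
      hr_in <- apply_mask(hr, mask_r)
      hd_in <- apply_mask(hd, mask_d)
      hr_new <- tanh(topo$m1 %*% (hd_in %*% w1) + m0_mult(topo, hd_in %*% w0))
      hd_new <- tanh(crossprod(topo$m1, hr_in %*% w1) +
                     m0_tmult(topo, hr_in %*% w0))
      if (keep_cache) {
        cache$mask_r[r] <- list(mask_r); cache$mask_d[r] <- list(mask_d)
        cache$in_r[[r]] <- hr_in; cache$in_d[[r]] <- hd_in
        cache$hr[[r + 1]] <- hr_new; cache$hd[[r + 1]] <- hd_new
      }
      hr <- hr_new; hd <- hd_new
    }
  }
  out <- list(drug = hr, disease = hd)
  if (keep_cache) attr(out, "cache") <- cache
  out
}

# Backward pass of message passing. grad_r/grad_d are dL/dH at the final
# round. Returns gradients for the embedding tables and round weights.
message_passing_backward <- function(topo, params, n_rounds, cache,
                                     grad_r, grad_d) {
  n <- topo$n; m <- topo$m
  g_t0 <- array(0, dim(params$table$t0))
  g_t1 <- array(0, dim(params$table$t1))
  g_rounds <- if (n_rounds > 1)
    lapply(seq_len(n_rounds - 1),
           function(r) list(w0 = array(0, dim(params$rounds[[r]]$w0)),
                            w1 = array(0, dim(params$rounds[[r]]$w1))))
  for (r in rev(seq_len(n_rounds))) {
    hr <- cache$hr[[r]]; hd <- cache$hd[[r]]
    gpre_r <- grad_r * (1 - hr^2)
    gpre_d <- grad_d * (1 - hd^2)
    if (r > 1) {
      w0 <- params$rounds[[r - 1]]$w0; w1 <- params$rounds[[r - 1]]$w1
      hr_in <- cache$in_r[[r - 1]]; hd_in <- cache$in_d[[r - 1]]
      # P_r = M1 (hd_in w1) + M0 (hd_in w0); P_d = M1' (hr_in w1) + M0' (hr_in w0)
      m1t_gr <- crossprod(topo$m1, gpre_r)   # m x h
      m0t_gr <- m0_tmult(topo, gpre_r)       # m x h
      m1_gd <- topo$m1 %*% gpre_d            # n x h
      m0_gd <- m0_mult(topo, gpre_d)         # n x h
      g_rounds[[r - 1]]$w1 <- crossprod(hd_in, m1t_gr) + crossprod(hr_in, m1_gd)
      g_rounds[[r - 1]]$w0 <- crossprod(hd_in, m0t_gr) + crossprod(hr_in, m0_gd)
      g_hd_in <- m1t_gr %*% t(w1) + m0t_gr %*% t(w0)
      g_hr_in <- m1_gd %*% t(w1) + m0_gd %*% t(w0)
      grad_d <- apply_mask(g_hd_in, cache$mask_d[[r - 1]])
      grad_r <- apply_mask(g_hr_in, cache$mask_r[[r - 1]])
    } else {
      # round 1: inputs are the embedding-table rows
      g_t1[n + seq_len(m), ] <- g_t1[n + seq_len(m), ] + crossprod(topo$m1, gpre_r)
      g_t0[n + seq_len(m), ] <- g_t0[n + seq_len(m), ] + m0_tmult(topo, gpre_r)
      g_t1[seq_len(n), ] <- g_t1[seq_len(n), ] + topo$m1 %*% gpre_d
      g_t0[seq_len(n), ] <- g_t0[seq_len(n), ] + m0_mult(topo, gpre_d)
    }
  }
  g_t0 <- apply_mask(g_t0, cache$mask_t0)
  g_t1 <- apply_mask(g_t1, cache$mask_t1)
  list(table = list(t0 = g_t0, t1 = g_t1), rounds = g_rounds)
}

#' Linear output transform of the topology module
#'
#' Applies the shared weight matrix `W` to the hidden states of both drug and
#' disease nodes, `z_i = W h_i` (row-wise `H %*% t(W)` in matrix form; with a
#' square symmetric-role `W` stored directly as `h x h`, `H %*% W`).
#'
#' @param hidden node hidden-state matrix.
#' @param w shared dense weight matrix.
#' @return embedding matrix of the same row count.
#' @export
dense_transform <- function(hidden, w) {
  if (ncol(hidden) != nrow(w)) stop("dense transform shape mismatch", call. = FALSE)
  hidden %*% w
}
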