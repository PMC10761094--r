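# Feature-space graphs: each entity is linked to itself and to its k most
# similar peers (extended k-nearest neighbourhood). The directed top-k
# selection is symmetrised by union so that the symmetric normalisation
# D^{-1/2} A D^{-1/2} is well defined.

#' Build the extended k-nearest-neighbour adjacency of a similarity matrix
#'
#' Row `i` of the directed selection holds ones at `i` itself and at the `k`
#' columns most similar to `i` (self-similarity never counts toward the `k`);
#' ties are broken by ascending column index. The result is then symmetrised
#' as `A <- (A + t(A)) > 0`.
#'
#' @param sim square similarity matrix ([similarity_matrix()] or plain).
#' @param k neighbour count, `1 <= k <= n - 1`.
#' @param symmetrize union-symmetrise (default `TRUE`); `FALSE` returns the
#'   raw directed selection, mainly for testing.
#' @return binary n x n matrix with unit diagonal.
#' @export
build_knn_adjacency <- function(sim, k, symmetrize = TRUE) {
  S <- unclass(sim)
  n <- nrow(S)
  if (k < 1 || k > n - 1)
    stop(sprintf("k must be in [1, %d], got %s", n - 1, format(k)), call. = FALSE)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- S[i, ]
    s[i] <- -Inf
    # secondary key enforces ascending-index tie-break
    nb <- order(-s, seq_along(s))[seq_len(k)]
    A[i, c(i, nb)] <- 1
  }
  if (symmetrize) A <- (A + t(A) > 0) * 1
  dimnames(A) <- dimnames(S)
  A
}

#' Symmetric normalisation of an adjacency matrix
#'
#' Returns `D^{-1/2} A D^{-1/2}` with `D` the diagonal degree matrix of `A`.
#' Self-loops guarantee every degree is positive for kNN graphs.
#'
#' @param adjacency symmetric binary matrix.
#' @return real symmetric matrix of the same shape.
#' @export
normalize_adjacency <- function(adjacency) {
  deg <- rowSums(adjacency)
  if (any(deg == 0))
    stop("zero-degree node in adjacency; cannot normalise", call. = FALSE)
  dinv <- 1 / sqrt(deg)
  adjacency * outer(dinv, dinv)
}

#' Build a kNN feature graph with its propagation operator
#'
#' @inheritParams build_knn_adjacency
#' @return a `drf_knn_graph` list: `adjacency`, `operator`
#'   (`D^{-1/2} A D^{-1/2}`), `k`.
#' @export
knn_graph <- function(sim, k) {
  A <- build_knn_adjacency(sim, k)
  structure(list(adjacency = A, operator = normalize_adjacency(A), k = k),
            class = "drf_knn_graph")
}

#' Export an adjacency matrix as an edge-list tibble
#'
#' @param adjacency binary matrix (optionally with dimnames).
#' @param upper_only keep each undirected edge once (default `TRUE`).
#' @return tibble with columns `from`, `to`.
#' @export
adjacency_edgelist <- function(adjacency, upper_only = TRUE) {
  idx <- which(adjacency != 0, arr.ind = TRUE)
  if (upper_only) idx <- idx[idx[, 1] <= idx[, 2], , drop = FALSE]
  lab <- function(nm, i) if (is.null(nm)) as.character(i) else nm[i]
  tibble::tibble(from = lab(rownames(adjacency), idx[, 1]),
                 to = lab(colnames(adjacency), idx[, 2]))
}
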