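# Feature-space propagation: a standard GCN over the kNN graph,
# Z^(l) = ReLU( A_hat Z^(l-1) W^(l) ), seeded with the similarity matrix
# itself as node features (Z^(0) = X).

#' Forward pass of the feature-space GCN
#'
#' Applies `Z^(l) = ReLU(A_hat Z^(l-1) W^(l))` for each layer, starting from
#' the similarity matrix as input features. During training, dropout is
#' applied to every layer's input.
#'
#' @param graph a [knn_graph()] whose `operator` is the symmetric-normalised
#'   adjacency.
#' @param x input feature matrix `Z^(0)` (normally the similarity matrix the
#'   graph was built from).
#' @param weights list of layer weight matrices `W^(l)`; layer 1 maps the
#'   input dimension to the hidden width.
#' @param training logical; enables dropout.
#' @param dropout dropout rate used when `training = TRUE`.
#' @param keep_cache return intermediate activations for backpropagation.
#' @return final-layer embedding matrix, with attribute `"cache"` when
#'   requested.
#' @export
feature_gcn_forward <- function(graph, x, weights, training = FALSE,
                                dropout = 0, keep_cache = FALSE) {
  op <- if (inherits(graph, "drf_knn_graph")) graph$operator else graph
  if (ncol(op) != nrow(x))
    stop("graph operator and feature dimensions disagree", call. = FALSE)
  z <- unclass(x)
  cache <- list(inputs = list(), pre = list(), masks = list())
  for (l in seq_along(weights)) {
    if (nrow(weights[[l]]) != ncol(z))
      stop(sprintf("feature GCN layer %d expects input width %d, got %d",
                   l, nrow(weights[[l]]), ncol(z)), call. = FALSE)
    mask <- if (training) dropout_mask(nrow(z), ncol(z), dropout) else NULL
    zin <- apply_mask(z, mask)
    pre <- op %*% zin %*% weights[[l]]
    z <- relu(pre)
    if (keep_cache) {
      cache$inputs[[l]] <- zin
      cache$pre[[l]] <- pre
      cache$masks[l] <- list(mask)
    }
  }
  if (keep_cache) attr(z, "cache") <- cache
  z
}

# Gradient of the feature GCN. `grad_out` is dL/d(final embedding); returns
# dL/dW per layer (input features are constants, so no input gradient).
feature_gcn_backward <- function(graph, weights, cache, grad_out) {
  op <- if (inherits(graph, "drf_knn_graph")) graph$operator else graph
  g <- grad_out
  dW <- vector("list", length(weights))
  for (l in rev(seq_along(weights))) {
    gpre <- g * (cache$pre[[l]] > 0)
    dW[[l]] <- crossprod(cache$inputs[[l]], op %*% gpre)
    if (l > 1) {
      gin <- (op %*% gpre) %*% t(weights[[l]])
      g <- apply_mask(gin, cache$masks[[l]])
    }
  }
  dW
}
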