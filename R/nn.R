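# Small neural-net primitives shared by the forward/backward passes.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

glorot_vec <- function(len) {
  lim <- sqrt(6 / (len + 1))
  stats::runif(len, -lim, lim)
}

# Inverted dropout: mask has expectation 1, so evaluation needs no rescale.
# Returned as a plain vector in column-major order; elementwise products
# against a matrix of matching length keep the matrix shape.
dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  (stats::runif(nr * nc) >= rate) / (1 - rate)
}

apply_mask <- function(x, mask) if (is.null(mask)) x else x * mask

#' Initialise all trainable parameters
#'
#' Weight matrices are Glorot-uniform (variance `2 / (fan_in + fan_out)`),
#' biases zero. Draw order is fixed — feature GCN (drug layers, disease
#' layers), topology tables and round weights, shared dense transform,
#' attention (drug then disease), MLP — so a seed fully determines the
#' initial state.
#'
#' @param n,m numbers of drugs and diseases.
#' @param config a [model_config()].
#' @return named list of parameter arrays (a `drf_params`).
#' @keywords internal
init_params <- function(n, m, config) {
  h <- config$hidden; hp <- config$attention_hidden
  use_f <- config$ablation != "w/o-f"
  use_t <- config$ablation != "w/o-t"
  p <- list()
  if (use_f) {
    dims_r <- c(n, rep(h, config$feature_layers))
    dims_d <- c(m, rep(h, config$feature_layers))
    p$feat_drug <- lapply(seq_len(config$feature_layers),
                          function(l) glorot(dims_r[l], dims_r[l + 1]))
    p$feat_dis <- lapply(seq_len(config$feature_layers),
                         function(l) glorot(dims_d[l], dims_d[l + 1]))
  }
  if (use_t) {
    p$topo_table <- list(t0 = glorot(n + m, h), t1 = glorot(n + m, h))
    if (config$topology_rounds > 1) {
      p$topo_round <- lapply(seq_len(config$topology_rounds - 1),
                             function(r) list(w0 = glorot(h, h),
                                              w1 = glorot(h, h)))
    }
    p$topo_dense <- glorot(h, h)
  }
  if (use_f && use_t && config$ablation != "w/o-a") {
    p$att_drug <- list(WF = glorot(hp, h), bF = numeric(hp),
                       WT = glorot(hp, h), bT = numeric(hp),
                       q = glorot_vec(hp))
    p$att_dis <- list(WF = glorot(hp, h), bF = numeric(hp),
                      WT = glorot(hp, h), bT = numeric(hp),
                      q = glorot_vec(hp))
  }
  h1 <- config$mlp_hidden[1]; h2 <- config$mlp_hidden[2]
  p$mlp <- list(W1 = glorot(2 * h, h1), b1 = numeric(h1),
                W2 = glorot(h1, h2), b2 = numeric(h2),
                w3 = glorot_vec(h2), b3 = 0)
  p
}

# Flatten a nested parameter list to a flat named list of numeric arrays
# (used by Adam and by the finite-difference gradient checker).
flatten_params <- function(p, prefix = "") {
  out <- list()
  nms <- names(p)
  for (i in seq_along(p)) {
    nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else as.character(i)
    key <- if (prefix == "") nm else paste0(prefix, ".", nm)
    if (is.list(p[[i]])) out <- c(out, flatten_params(p[[i]], key))
    else out[[key]] <- p[[i]]
  }
  out
}

set_param <- function(p, key, value) {
  path <- strsplit(key, ".", fixed = TRUE)[[1]]
  expr <- Reduce(function(acc, k) {
    if (grepl("^[0-9]+$", k)) call("[[", acc, as.integer(k))
    else call("[[", acc, k)
  }, path, init = quote(p))
  eval(call("<-", expr, value))
  p
}
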