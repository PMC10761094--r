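# End-to-end model: the two space-specific encoders, attention fusion,
# consistency regularisation and MLP scoring are trained jointly by
# full-batch gradient descent (Adam) on
#   L = L_bce + lambda * (L_Cr + L_Cd).
# The backward pass is written by hand in the same matrix algebra as the
# forward pass; a finite-difference check in the test suite guards it.

model_spaces <- function(config) {
  list(feature = config$ablation != "w/o-f",
       topology = config$ablation != "w/o-t")
}

# One full forward pass. `st` carries the immutable per-run state (graphs,
# inputs, pair list); returns losses, scores and every cache needed by the
# backward pass.
model_forward <- function(st, params, config, training = FALSE,
                          keep_cache = FALSE) {
  sp <- model_spaces(config)
  gamma <- config$dropout
  out <- list()
  if (sp$feature) {
    out$z_fr <- feature_gcn_forward(st$kg_r, st$x_r, params$feat_drug,
                                    training, gamma, keep_cache)
    out$z_fd <- feature_gcn_forward(st$kg_d, st$x_d, params$feat_dis,
                                    training, gamma, keep_cache)
  }
  if (sp$topology) {
    out$mp <- message_passing_forward(
      st$topo, list(table = params$topo_table, rounds = params$topo_round),
      config$topology_rounds, training, gamma, keep_cache)
    out$z_tr <- dense_transform(out$mp$drug, params$topo_dense)
    out$z_td <- dense_transform(out$mp$disease, params$topo_dense)
  }
  if (sp$feature && sp$topology) {
    if (config$ablation == "w/o-a") {
      half <- function(zf, zt) list(fused = (zf + zt) / 2,
                                    weights = list(alpha_f = rep(0.5, nrow(zf)),
                                                   alpha_t = rep(0.5, nrow(zf))))
      out$att_r <- half(out$z_fr, out$z_tr)
      out$att_d <- half(out$z_fd, out$z_td)
    } else {
      out$att_r <- attention_forward(out$z_fr, out$z_tr, params$att_drug,
                                     keep_cache = keep_cache)
      out$att_d <- attention_forward(out$z_fd, out$z_td, params$att_dis,
                                     keep_cache = keep_cache)
    }
    out$z_r <- out$att_r$fused
    out$z_d <- out$att_d$fused
  } else if (sp$feature) {
    out$z_r <- out$z_fr; out$z_d <- out$z_fd
  } else {
    out$z_r <- out$z_tr; out$z_d <- out$z_td
  }
  out$scores <- predict_pairs(out$z_r, out$z_d, params$mlp, st$pairs,
                              training, gamma, keep_cache)
  l_bce <- bce_loss(as.numeric(out$scores), st$labels)
  l_cr <- l_cd <- 0
  if (sp$feature && sp$topology && config$lambda > 0) {
    out$cons_r <- consistency_backward(out$z_fr, out$z_tr)
    out$cons_d <- consistency_backward(out$z_fd, out$z_td)
    l_cr <- out$cons_r$loss
    l_cd <- out$cons_d$loss
  }
  out$loss <- c(l_bce = l_bce, l_cr = l_cr, l_cd = l_cd,
                l_total = l_bce + config$lambda * (l_cr + l_cd))
  out
}

# One Adam step over the nested parameter/gradient trees. `state` carries
# first/second moment trees of the same shape; returns updated trees.
adam_step <- function(p, g, m, v, lr, b1, b2, eps, bc1, bc2) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      res <- adam_step(p[[i]], g[[i]], m[[i]], v[[i]], lr, b1, b2, eps, bc1, bc2)
      p[[i]] <- res$p; m[[i]] <- res$m; v[[i]] <- res$v
    }
    return(list(p = p, m = m, v = v))
  }
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  list(p = p - lr * (m / bc1) / (sqrt(v / bc2) + eps), m = m, v = v)
}

zero_like <- function(p) if (is.list(p)) lapply(p, zero_like) else p * 0

# Scatter per-pair gradients back to per-node embedding gradients.
scatter_pair_grad <- function(grad_pairs, idx, n_nodes) {
  out <- matrix(0, n_nodes, ncol(grad_pairs))
  agg <- rowsum(grad_pairs, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

model_backward <- function(st, params, config, fwd) {
  sp <- model_spaces(config)
  n <- length(st$labels)
  grads <- list()
  d_logits <- as.numeric(fwd$scores) - st$labels
  mb <- mlp_backward(params$mlp, attr(fwd$scores, "cache"), d_logits)
  grads$mlp <- mb$pars
  h <- ncol(fwd$z_r)
  d_zr <- scatter_pair_grad(mb$x1[, seq_len(h), drop = FALSE],
                            st$pairs[, 1], nrow(fwd$z_r))
  d_zd <- scatter_pair_grad(mb$x1[, h + seq_len(h), drop = FALSE],
                            st$pairs[, 2], nrow(fwd$z_d))
  d_zfr <- d_ztr <- d_zfd <- d_ztd <- NULL
  if (sp$feature && sp$topology) {
    if (config$ablation == "w/o-a") {
      d_zfr <- d_zr / 2; d_ztr <- d_zr / 2
      d_zfd <- d_zd / 2; d_ztd <- d_zd / 2
    } else {
      ab_r <- attention_backward(fwd$z_fr, fwd$z_tr, params$att_drug,
                                 fwd$att_r, d_zr)
      ab_d <- attention_backward(fwd$z_fd, fwd$z_td, params$att_dis,
                                 fwd$att_d, d_zd)
      grads$att_drug <- ab_r$pars
      grads$att_dis <- ab_d$pars
      d_zfr <- ab_r$z_f; d_ztr <- ab_r$z_t
      d_zfd <- ab_d$z_f; d_ztd <- ab_d$z_t
    }
    if (config$lambda > 0) {
      d_zfr <- d_zfr + config$lambda * fwd$cons_r$z_f
      d_ztr <- d_ztr + config$lambda * fwd$cons_r$z_t
      d_zfd <- d_zfd + config$lambda * fwd$cons_d$z_f
      d_ztd <- d_ztd + config$lambda * fwd$cons_d$z_t
    }
  } else if (sp$feature) {
    d_zfr <- d_zr; d_zfd <- d_zd
  } else {
    d_ztr <- d_zr; d_ztd <- d_zd
  }
  if (sp$feature) {
    grads$feat_drug <- feature_gcn_backward(st$kg_r, params$feat_drug,
                                            attr(fwd$z_fr, "cache"), d_zfr)
    grads$feat_dis <- feature_gcn_backward(st$kg_d, params$feat_dis,
                                           attr(fwd$z_fd, "cache"), d_zfd)
  }
  if (sp$topology) {
    grads$topo_dense <- crossprod(fwd$mp$drug, d_ztr) +
      crossprod(fwd$mp$disease, d_ztd)
    d_hr <- d_ztr %*% t(params$topo_dense)
    d_hd <- d_ztd %*% t(params$topo_dense)
    mpb <- message_passing_backward(
      st$topo, list(table = params$topo_table, rounds = params$topo_round),
      config$topology_rounds, attr(fwd$mp, "cache"), d_hr, d_hd)
    grads$topo_table <- mpb$table
    if (config$topology_rounds > 1) grads$topo_round <- mpb$rounds
  }
  grads
}

# Reorder a gradient list to the exact structure of the parameter list so the
# two unlist() to aligned vectors.
align_like <- function(template, x) {
  if (!is.list(template)) return(x)
  out <- template
  nms <- names(template)
  for (i in seq_along(template)) {
    key <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else i
    out[[i]] <- align_like(template[[i]], x[[key]])
  }
  out
}

#' Train the dual-space association model
#'
#' Builds the kNN feature graphs and the typed bipartite topology graph,
#' initialises all parameters from `config$seed`, and runs `config$epochs`
#' full-batch Adam steps on the joint objective. Training pairs are all
#' drug-disease pairs selected by `train_mask`: the positives among them form
#' the type-1 topology edges and every selected pair contributes a BCE term
#' (unknown pairs act as negatives; no negative sampling).
#'
#' @param data list with `drug_sim`, `disease_sim`, `assoc` (as returned by
#'   [read_dataset_dir()], [generate_planted_dataset()] or [toy_fixture()]).
#' @param config a [model_config()].
#' @param train_mask logical n x m matrix marking training-visible pairs;
#'   default all pairs.
#' @return a `drf_model` with elements `params`, `config`, `history`
#'   (per-epoch loss breakdown tibble), `embeddings` (evaluation-mode
#'   `z_fr`, `z_tr`, `z_fd`, `z_td`, `z_r`, `z_d`), `attention` (per-node
#'   weights, when enabled), `graphs`, `train_mask`, `drug_ids`,
#'   `disease_ids`.
#' @export
#' @examples
#' fit <- train_model(toy_fixture(), model_config(epochs = 50, k = 1,
#'                                                hidden = 8,
#'                                                attention_hidden = 4,
#'                                                seed = 1))
#' glance(fit)
train_model <- function(data, config = model_config(), train_mask = NULL) {
  stopifnot(inherits(config, "drf_config"))
  Y <- unclass(data$assoc)
  n <- nrow(Y); m <- ncol(Y)
  if (is.null(train_mask)) train_mask <- matrix(TRUE, n, m)
  pairs <- which(train_mask, arr.ind = TRUE)
  if (nrow(pairs) == 0) stop("empty training mask", call. = FALSE)
  labels <- Y[pairs]
  if (all(labels == 0) || all(labels == 1))
    stop("training pairs must include both labels", call. = FALSE)
  sp <- model_spaces(config)
  st <- list(pairs = pairs, labels = labels)
  if (sp$feature) {
    st$kg_r <- knn_graph(data$drug_sim, config$k)
    st$kg_d <- knn_graph(data$disease_sim, config$k)
    st$x_r <- unclass(data$drug_sim)
    st$x_d <- unclass(data$disease_sim)
  }
  if (sp$topology) st$topo <- build_topology_graph(Y, train_mask)

  set.seed(config$seed)
  params <- init_params(n, m, config)
  adam_m <- zero_like(params)
  adam_v <- zero_like(params)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- matrix(NA_real_, config$epochs, 4,
                    dimnames = list(NULL, c("l_bce", "l_cr", "l_cd", "l_total")))
  for (epoch in seq_len(config$epochs)) {
    fwd <- model_forward(st, params, config, training = config$dropout > 0,
                         keep_cache = TRUE)
    if (!is.finite(fwd$loss[["l_total"]]))
      stop(sprintf("training diverged at epoch %d (non-finite loss)", epoch),
           call. = FALSE)
    history[epoch, ] <- fwd$loss
    grads <- align_like(params, model_backward(st, params, config, fwd))
    upd <- adam_step(params, grads, adam_m, adam_v, config$learning_rate,
                     b1, b2, eps, 1 - b1^epoch, 1 - b2^epoch)
    params <- upd$p; adam_m <- upd$m; adam_v <- upd$v
    if (config$verbose > 0 && epoch %% config$verbose == 0)
      message(sprintf("epoch %d: L = %.4f (bce %.4f, cons %.4f/%.4f)",
                      epoch, fwd$loss[["l_total"]], fwd$loss[["l_bce"]],
                      fwd$loss[["l_cr"]], fwd$loss[["l_cd"]]))
  }
  final <- model_forward(st, params, config, training = FALSE)
  attention <- NULL
  if (sp$feature && sp$topology && config$ablation != "w/o-a") {
    attention <- dplyr::bind_rows(
      tibble::tibble(kind = "drug", node = rownames(Y) %||% as.character(seq_len(n)),
                     alpha_feature = final$att_r$weights$alpha_f,
                     alpha_topology = final$att_r$weights$alpha_t),
      tibble::tibble(kind = "disease", node = colnames(Y) %||% as.character(seq_len(m)),
                     alpha_feature = final$att_d$weights$alpha_f,
                     alpha_topology = final$att_d$weights$alpha_t))
  }
  structure(list(
    params = params, config = config,
    history = dplyr::mutate(tibble::as_tibble(history),
                            lambda = config$lambda,
                            epoch = dplyr::row_number(), .before = 1),
    embeddings = final[intersect(c("z_fr", "z_tr", "z_fd", "z_td", "z_r", "z_d"),
                                 names(final))],
    attention = attention,
    graphs = st[intersect(c("kg_r", "kg_d", "topo"), names(st))],
    train_mask = train_mask,
    drug_ids = rownames(Y) %||% paste0("d", seq_len(n) - 1L),
    disease_ids = colnames(Y) %||% paste0("s", seq_len(m) - 1L)
  ), class = "drf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict association scores from a trained model
#'
#' @param object a `drf_model`.
#' @param pairs optional two-column matrix of (drug, disease) indices;
#'   default: every pair.
#' @param ... unused.
#' @return if `pairs` is `NULL`, the full n x m score matrix; otherwise a
#'   tibble with columns `drug`, `disease`, `score`.
#' @export
predict.drf_model <- function(object, pairs = NULL, ...) {
  emb <- object$embeddings
  full <- is.null(pairs)
  n <- nrow(emb$z_r); m <- nrow(emb$z_d)
  if (full)
    pairs <- as.matrix(expand.grid(drug = seq_len(n), disease = seq_len(m)))
  s <- predict_pairs(emb$z_r, emb$z_d, object$params$mlp, pairs)
  if (full) {
    out <- matrix(s, n, m, dimnames = list(object$drug_ids, object$disease_ids))
    return(out)
  }
  tibble::tibble(drug = object$drug_ids[pairs[, 1]],
                 disease = object$disease_ids[pairs[, 2]],
                 score = as.numeric(s))
}

#' Ranked novel-association candidates
#'
#' Scores every pair not known to be positive in training and returns them
#' ranked by predicted score — the case-study workflow of inspecting a
#' model's top repositioning candidates.
#'
#' @param model a `drf_model`.
#' @param assoc the association matrix the model was trained on.
#' @param top_n how many candidates to keep (default all).
#' @return tibble `drug`, `disease`, `score`, sorted decreasing.
#' @export
rank_candidates <- function(model, assoc, top_n = Inf) {
  scores <- predict(model)
  known <- unclass(assoc) == 1
  idx <- which(!known, arr.ind = TRUE)
  out <- tibble::tibble(drug = model$drug_ids[idx[, 1]],
                        disease = model$disease_ids[idx[, 2]],
                        score = scores[idx]) |>
    dplyr::arrange(dplyr::desc(.data$score))
  if (is.finite(top_n)) out <- utils::head(out, top_n)
  out
}

#' @export
print.drf_model <- function(x, ...) {
  cat(sprintf("<dual-space association model: %d drugs x %d diseases>\n",
              length(x$drug_ids), length(x$disease_ids)))
  cat(sprintf("  epochs %d, k = %d, lambda = %g, ablation = %s\n",
              x$config$epochs, x$config$k, x$config$lambda, x$config$ablation))
  cat(sprintf("  final loss: %.4f (bce %.4f)\n",
              utils::tail(x$history$l_total, 1), utils::tail(x$history$l_bce, 1)))
  invisible(x)
}
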