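#' Model configuration
#'
#' All hyperparameters of the dual-space model in one validated list. The
#' defaults follow the reference experimental setting: 4000 training epochs,
#' learning rate 0.01, dropout 0.3, K = 4 feature-graph neighbours and
#' consistency trade-off lambda = 0.1 (0.01 suits very sparse datasets).
#'
#' @param epochs number of full-batch training epochs.
#' @param learning_rate Adam step size.
#' @param dropout dropout rate gamma in `[0, 1)`, applied to feature-GCN layer
#'   inputs, topology hidden states between rounds, and MLP hidden layers.
#' @param k neighbour count for the kNN feature graphs.
#' @param lambda trade-off weight of the two consistency terms.
#' @param hidden embedding width h shared by both spaces.
#' @param attention_hidden attention transform width h'.
#' @param feature_layers number of feature-GCN layers.
#' @param topology_rounds message-passing rounds over the bipartite graph.
#' @param mlp_hidden integer vector of the two MLP hidden widths; defaults to
#'   `c(hidden, hidden / 2)`.
#' @param ablation `"none"`, or one of `"w/o-l"` (no consistency terms),
#'   `"w/o-a"` (attention frozen at 0.5/0.5), `"w/o-f"` (feature space
#'   removed), `"w/o-t"` (topology space removed).
#' @param seed integer seed controlling initialisation and dropout.
#' @param verbose print the loss every `verbose` epochs (0 = silent).
#' @return a `drf_config` list.
#' @export
model_config <- function(epochs = 4000, learning_rate = 0.01, dropout = 0.3,
                         k = 4, lambda = 0.1, hidden = 64,
                         attention_hidden = 32, feature_layers = 2,
                         topology_rounds = 2, mlp_hidden = NULL,
                         ablation = c("none", "w/o-l", "w/o-a", "w/o-f", "w/o-t"),
                         seed = 1, verbose = 0) {
  ablation <- match.arg(ablation)
  if (is.null(mlp_hidden)) mlp_hidden <- c(hidden, max(1L, hidden %/% 2L))
  stopifnot(epochs >= 1, learning_rate > 0, dropout >= 0, dropout < 1,
            k >= 1, lambda >= 0, hidden >= 1, attention_hidden >= 1,
            feature_layers >= 1, topology_rounds >= 1,
            length(mlp_hidden) == 2)
  if (ablation == "w/o-l") lambda <- 0
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 dropout = dropout, k = as.integer(k), lambda = lambda,
                 hidden = as.integer(hidden),
                 attention_hidden = as.integer(attention_hidden),
                 feature_layers = as.integer(feature_layers),
                 topology_rounds = as.integer(topology_rounds),
                 mlp_hidden = as.integer(mlp_hidden),
                 ablation = ablation, seed = as.integer(seed),
                 verbose = as.integer(verbose)),
            class = "drf_config")
}

#' Read a model configuration from a YAML file
#'
#' Fields mirror the arguments of [model_config()]; unknown fields error.
#'
#' @param path YAML file.
#' @return a `drf_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- setdiff(names(formals(model_config)), "...")
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0)
    stop(sprintf("unknown config fields: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  do.call(model_config, vals)
}
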