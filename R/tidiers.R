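# broom-style accessors and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained model into per-node attention weights
#'
#' @param x a `drf_model`.
#' @param ... unused.
#' @return tibble `kind`, `node`, `alpha_feature`, `alpha_topology` (empty
#'   when the model was trained without attention).
#' @export
tidy.drf_model <- function(x, ...) {
  x$attention %||% tibble::tibble(kind = character(), node = character(),
                                  alpha_feature = numeric(),
                                  alpha_topology = numeric())
}

#' One-row summary of a trained model
#'
#' @param x a `drf_model`.
#' @param ... unused.
#' @return tibble with dimensions, configuration highlights and final losses.
#' @export
glance.drf_model <- function(x, ...) {
  last <- utils::tail(x$history, 1)
  tibble::tibble(n_drugs = length(x$drug_ids),
                 n_diseases = length(x$disease_ids),
                 epochs = x$config$epochs, k = x$config$k,
                 lambda = x$config$lambda, ablation = x$config$ablation,
                 l_bce = last$l_bce, l_cr = last$l_cr, l_cd = last$l_cd,
                 l_total = last$l_total)
}

#' @export
tidy.drf_cv <- function(x, ...) x$folds

#' @export
glance.drf_cv <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd_folds", "sd_repeats"))
}

#' @export
tidy.drf_coldstart <- function(x, ...) x$per_drug

#' @export
glance.drf_coldstart <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "metric",
                     values_from = c("mean", "sd"))
}

#' Plot the training loss history
#'
#' @param object a `drf_model`.
#' @param ... unused.
#' @return a ggplot of the loss components against epoch.
#' @export
autoplot.drf_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("l_bce", "l_cr", "l_cd", "l_total"),
                              names_to = "component", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object a `drf_cv`.
#' @param ... unused.
#' @return a ggplot with one panel per metric.
#' @export
autoplot.drf_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$folds, c("auroc", "auprc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$repeat_id),
                                     y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "repeat", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the attention weight distributions
#'
#' @param object a `drf_attention_report`.
#' @param ... unused.
#' @return a ggplot of per-node fusion weights by entity kind and space.
#' @export
autoplot.drf_attention_report <- function(object, ...) {
  ggplot2::ggplot(object$per_node,
                  ggplot2::aes(x = interaction(.data$kind, .data$space, sep = "-"),
                               y = .data$alpha)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "attention weight") +
    ggplot2::theme_minimal()
}
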