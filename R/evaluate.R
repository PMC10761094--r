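# Ranking metrics. AUROC is computed from the rank statistic (Mann-Whitney,
# ties averaged); AUPRC by step integration of the precision-recall curve
# with tied scores grouped into a single threshold.

#' Area under the ROC curve
#'
#' Rank-statistic form with midranks for ties:
#' `(mean positive rank - (P + 1) / 2) / N_negative`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: test set has a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Scores are swept from high to low; at each distinct threshold the
#' precision/recall point is recorded and the curve is integrated as a step
#' function, `sum((R_k - R_(k-1)) * P_k)`.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  n1 <- sum(labels == 1)
  if (n1 == 0 || n1 == length(labels))
    stop("AUPRC undefined: test set has a single class", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]; s <- scores[o]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  tp <- tp[keep]; fp <- fp[keep]
  prec <- tp / (tp + fp)
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

#' Evaluate predictions on a held-out pair set
#'
#' @param scores full n x m score matrix (or a vector aligned with
#'   `test_pairs`).
#' @param labels binary association matrix (or aligned vector).
#' @param test_pairs two-column matrix of held-out (drug, disease) indices;
#'   omit when `scores`/`labels` are already vectors.
#' @return one-row tibble `auroc`, `auprc`, `n_pairs`, `n_positive`.
#' @export
evaluate <- function(scores, labels, test_pairs = NULL) {
  if (!is.null(test_pairs)) {
    scores <- scores[test_pairs]
    labels <- unclass(labels)[test_pairs]
  }
  if (length(scores) == 0) stop("empty test pair set", call. = FALSE)
  tibble::tibble(auroc = auroc(scores, labels),
                 auprc = auprc(scores, labels),
                 n_pairs = length(scores),
                 n_positive = sum(labels == 1))
}

#' Assign all drug-disease pairs to cross-validation folds
#'
#' All `n * m` pairs — positives and unknowns together — are permuted and
#' dealt into `n_folds` exclusive subsets whose sizes differ by at most one.
#'
#' @param n,m matrix dimensions.
#' @param n_folds fold count.
#' @param seed fold-assignment seed.
#' @return integer n x m matrix of fold labels `1..n_folds`.
#' @export
fold_split <- function(n, m, n_folds = 10, seed = 1) {
  stopifnot(n_folds >= 2, n_folds <= n * m)
  set.seed(seed)
  f <- sample(rep(seq_len(n_folds), length.out = n * m))
  matrix(f, n, m)
}

derive_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.double(master)
  for (k in ids) s <- (s * 131 + k) %% 2147483647
  as.integer(s)
}

#' Repeated k-fold cross-validation over all pairs
#'
#' For every repeat a fresh fold split of all pairs is drawn; each fold is
#' held out in turn, the model is trained on the remaining folds' pairs
#' (their positives form the topology graph; their unknowns are the BCE
#' negatives) and the held-out fold's pairs are scored. Per-repeat and
#' per-fold seeds are derived deterministically from `config$seed`.
#'
#' @param data dataset list (`drug_sim`, `disease_sim`, `assoc`).
#' @param config a [model_config()].
#' @param n_folds,n_repeats protocol size (reference protocol: 10 x 10).
#' @return a `drf_cv` list: `folds` — tibble with one row per evaluated fold
#'   (`repeat_id`, `fold`, `auroc`, `auprc`, ...); `summary` — mean and sd of
#'   both metrics over all evaluated folds and over repeat means.
#' @export
cross_validate <- function(data, config = model_config(), n_folds = 10,
                           n_repeats = 10) {
  Y <- unclass(data$assoc)
  n <- nrow(Y); m <- ncol(Y)
  rows <- list()
  for (rep_i in seq_len(n_repeats)) {
    folds <- fold_split(n, m, n_folds, seed = derive_seed(config$seed, 7, rep_i))
    for (fold_i in seq_len(n_folds)) {
      test_mask <- folds == fold_i
      test_pairs <- which(test_mask, arr.ind = TRUE)
      test_labels <- Y[test_pairs]
      if (all(test_labels == 0) || all(test_labels == 1)) {
        warning(sprintf("repeat %d fold %d has a single class; skipped",
                        rep_i, fold_i), call. = FALSE)
        next
      }
      cfg <- config
      cfg$seed <- derive_seed(config$seed, 11, rep_i, fold_i)
      fit <- train_model(data, cfg, train_mask = !test_mask)
      res <- evaluate(predict(fit), Y, test_pairs)
      rows[[length(rows) + 1]] <-
        dplyr::mutate(res, repeat_id = rep_i, fold = fold_i, .before = 1)
    }
  }
  folds_tbl <- dplyr::bind_rows(rows)
  if (nrow(folds_tbl) == 0)
    stop("no evaluable folds: every fold had a single class", call. = FALSE)
  rep_means <- folds_tbl |>
    dplyr::group_by(.data$repeat_id) |>
    dplyr::summarise(auroc = mean(.data$auroc), auprc = mean(.data$auprc),
                     .groups = "drop")
  summary <- tibble::tibble(
    metric = c("auroc", "auprc"),
    mean = c(mean(folds_tbl$auroc), mean(folds_tbl$auprc)),
    sd_folds = c(stats::sd(folds_tbl$auroc), stats::sd(folds_tbl$auprc)),
    sd_repeats = c(stats::sd(rep_means$auroc), stats::sd(rep_means$auprc)))
  structure(list(folds = folds_tbl, summary = summary,
                 n_folds = n_folds, n_repeats = n_repeats, config = config),
            class = "drf_cv")
}

#' @export
print.drf_cv <- function(x, ...) {
  cat(sprintf("<%d x %d-fold cross-validation, %d folds evaluated>\n",
              x$n_repeats, x$n_folds, nrow(x$folds)))
  print(x$summary)
  invisible(x)
}

#' Cold-start evaluation: predicting indications for new drugs
#'
#' For each drug with at least one known association, all of its pairs are
#' removed from training (the drug enters the model with no topology
#' positives — only its similarity profile); the model is retrained and the
#' drug's full disease row is scored against its held-out positives. Drugs
#' without associations are skipped: their metrics are undefined.
#'
#' @param data dataset list.
#' @param config a [model_config()].
#' @param max_drugs cap on the number of drugs tested (the full protocol
#'   trains one model per drug); drugs are taken in row order.
#' @return a `drf_coldstart` list: `per_drug` tibble (`drug`, `auroc`,
#'   `auprc`, `n_positive`) and `summary` (means over tested drugs).
#' @export
new_drug_evaluation <- function(data, config = model_config(), max_drugs = Inf) {
  Y <- unclass(data$assoc)
  n <- nrow(Y); m <- ncol(Y)
  if (sum(rowSums(Y) > 0) < 2)
    stop("cold-start protocol needs at least 2 drugs with associations",
         call. = FALSE)
  # metrics need both classes in the held-out disease row
  eligible <- which(rowSums(Y) > 0 & rowSums(Y) < m)
  if (is.finite(max_drugs)) eligible <- utils::head(eligible, max_drugs)
  rows <- list()
  for (i in eligible) {
    mask <- matrix(TRUE, n, m)
    mask[i, ] <- FALSE
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 13, i)
    fit <- train_model(data, cfg, train_mask = mask)
    scores <- predict(fit)
    res <- evaluate(scores[i, ], Y[i, ])
    rows[[length(rows) + 1]] <- dplyr::mutate(
      res, drug = rownames(Y)[i] %||% as.character(i), .before = 1)
  }
  per_drug <- dplyr::bind_rows(rows)
  structure(list(
    per_drug = per_drug,
    summary = tibble::tibble(metric = c("auroc", "auprc"),
                             mean = c(mean(per_drug$auroc), mean(per_drug$auprc)),
                             sd = c(stats::sd(per_drug$auroc), stats::sd(per_drug$auprc)),
                             n_drugs = nrow(per_drug))),
    class = "drf_coldstart")
}

#' @export
print.drf_coldstart <- function(x, ...) {
  cat(sprintf("<cold-start evaluation over %d drugs>\n", nrow(x$per_drug)))
  print(x$summary)
  invisible(x)
}

#' Hyperparameter sweep
#'
#' Runs [cross_validate()] once per candidate value of `k` (feature-graph
#' neighbours) or `lambda` (consistency trade-off), everything else fixed.
#' The reference protocol sweeps K over `c(1, 4, 8, 12, 16)` and lambda over
#' `c(0.001, 0.01, 0.1, 1, 10, 100)`.
#'
#' @param data dataset list.
#' @param config base configuration (its `seed` is shared by all rows).
#' @param parameter `"k"` or `"lambda"`.
#' @param values candidate values.
#' @param n_folds,n_repeats passed to [cross_validate()].
#' @return tibble with one row per (value, metric) from each CV summary.
#' @export
sweep_parameter <- function(data, config = model_config(),
                            parameter = c("k", "lambda"), values,
                            n_folds = 10, n_repeats = 1) {
  parameter <- match.arg(parameter)
  stopifnot(length(values) >= 1)
  purrr::map_dfr(values, function(v) {
    cfg <- config
    cfg[[parameter]] <- if (parameter == "k") as.integer(v) else v
    cv <- cross_validate(data, cfg, n_folds = n_folds, n_repeats = n_repeats)
    dplyr::mutate(cv$summary, parameter = parameter, value = v, .before = 1)
  })
}

#' Component ablation study
#'
#' Trains the full model and its four ablations — no consistency terms
#' (`w/o-l`), no attention (`w/o-a`), no feature space (`w/o-f`), no topology
#' space (`w/o-t`) — under identical held-out splits and seeds, one split per
#' seed, and evaluates each on the held-out pairs.
#'
#' @param data dataset list.
#' @param config base configuration; its `ablation` field is overridden.
#' @param seeds integer vector; each seed draws its own holdout split and
#'   initialisation.
#' @param holdout fraction of pairs held out per seed.
#' @return tibble with `seed`, `ablation`, `auroc`, `auprc`.
#' @export
ablation_study <- function(data, config = model_config(), seeds = 1:5,
                           holdout = 0.1) {
  Y <- unclass(data$assoc)
  n <- nrow(Y); m <- ncol(Y)
  variants <- c("none", "w/o-l", "w/o-a", "w/o-f", "w/o-t")
  purrr::map_dfr(seeds, function(s) {
    set.seed(derive_seed(s, 17))
    test_mask <- matrix(stats::runif(n * m) < holdout, n, m)
    tp <- which(test_mask, arr.ind = TRUE)
    purrr::map_dfr(variants, function(v) {
      cfg <- config
      cfg$ablation <- v
      if (v == "w/o-l") cfg$lambda <- 0
      cfg$seed <- derive_seed(s, 19)
      fit <- train_model(data, cfg, train_mask = !test_mask)
      res <- evaluate(predict(fit), Y, tp)
      tibble::tibble(seed = s, ablation = v,
                     auroc = res$auroc, auprc = res$auprc)
    })
  })
}

#' Per-node attention distribution report
#'
#' Summarises the learned fusion weights by entity kind and space — the
#' r-topology / r-feature / d-topology / d-feature distributions — alongside
#' the per-node weights themselves.
#'
#' @param model a trained `drf_model` with attention enabled.
#' @return a `drf_attention_report` list: `per_node` tibble (long form:
#'   `kind`, `node`, `space`, `alpha`) and `summary` (mean, quartiles per
#'   kind x space).
#' @export
attention_report <- function(model) {
  if (is.null(model$attention))
    stop("model was trained without the attention mechanism; nothing to report",
         call. = FALSE)
  per_node <- model$attention |>
    tidyr::pivot_longer(c("alpha_feature", "alpha_topology"),
                        names_to = "space", values_to = "alpha",
                        names_prefix = "alpha_")
  summary <- per_node |>
    dplyr::group_by(.data$kind, .data$space) |>
    dplyr::summarise(mean = mean(.data$alpha),
                     q25 = stats::quantile(.data$alpha, 0.25),
                     median = stats::median(.data$alpha),
                     q75 = stats::quantile(.data$alpha, 0.75),
                     .groups = "drop")
  structure(list(per_node = per_node, summary = summary),
            class = "drf_attention_report")
}

#' @export
print.drf_attention_report <- function(x, ...) {
  cat("<attention distribution report>\n")
  print(x$summary)
  invisible(x)
}
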