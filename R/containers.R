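#' Construct a validated similarity matrix
#'
#' A similarity matrix holds pairwise similarity scores between entities of a
#' single kind (drugs or diseases). Scores live in the unit interval, the
#' matrix is square and symmetric, and the diagonal is expected (not required)
#' to be 1: chemical-substructure similarity of a drug with itself, or
#' phenotype-semantic similarity of a disease with itself, is maximal by
#' construction.
#'
#' Asymmetry up to `tol` (floating-point artifacts in distributed files) is
#' repaired by averaging `(S + t(S)) / 2`; larger asymmetry is an error.
#'
#' @param values square numeric matrix with entries in `[0, 1]`.
#' @param entity_ids optional character vector of row/column labels; defaults
#'   to the dimnames of `values` or auto-generated labels.
#' @param entity_kind `"drug"` or `"disease"`.
#' @param tol symmetry tolerance (default `1e-8`).
#' @return a `drf_similarity` object: the numeric matrix with class and
#'   `entity_kind` attributes and dimnames set to `entity_ids`.
#' @export
#' @examples
#' similarity_matrix(diag(2), entity_kind = "drug")
similarity_matrix <- function(values, entity_ids = NULL,
                              entity_kind = c("drug", "disease"),
                              tol = 1e-8) {
  entity_kind <- match.arg(entity_kind)
  if (!is.matrix(values) || !is.numeric(values))
    stop("similarity values must be a numeric matrix", call. = FALSE)
  if (nrow(values) != ncol(values))
    stop(sprintf("similarity matrix must be square, got %d x %d",
                 nrow(values), ncol(values)), call. = FALSE)
  asym <- max(abs(values - t(values)))
  if (asym > tol)
    stop(sprintf("similarity matrix asymmetric beyond tolerance: max |S - t(S)| = %.3g > %.3g",
                 asym, tol), call. = FALSE)
  values <- (values + t(values)) / 2
  bad <- which(values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("similarity entries must lie in [0, 1]; first offender at (%d, %d): %g",
                 bad[1, 1], bad[1, 2], values[bad[1, 1], bad[1, 2]]), call. = FALSE)
  if (any(abs(diag(values) - 1) > tol))
    warning("similarity diagonal is not all 1; self-similarity is usually maximal",
            call. = FALSE)
  if (is.null(entity_ids)) entity_ids <- rownames(values)
  if (is.null(entity_ids))
    entity_ids <- paste0(if (entity_kind == "drug") "d" else "s",
                         seq_len(nrow(values)) - 1L)
  if (length(entity_ids) != nrow(values))
    stop("entity_ids length does not match matrix dimension", call. = FALSE)
  dimnames(values) <- list(entity_ids, entity_ids)
  structure(values, class = c("drf_similarity", "matrix", "array"),
            entity_kind = entity_kind)
}

#' Construct a validated drug-disease association matrix
#'
#' Rows are drugs, columns are diseases, entries are 0/1 labels: 1 marks a
#' validated treatment relationship. Orientation is fixed everywhere in the
#' package (drugs = rows); loaders transpose only on an explicit flag.
#'
#' @param values binary numeric matrix, `n` drugs by `m` diseases.
#' @param drug_ids,disease_ids optional labels; auto-named `d0..` / `s0..`
#'   when absent.
#' @param n_associations optional declared association count; validated
#'   against the realized count when supplied.
#' @return a `drf_association` object (binary matrix with labels).
#' @export
#' @examples
#' association_matrix(matrix(c(1, 1, 0, 0, 1, 0), nrow = 3))
association_matrix <- function(values, drug_ids = NULL, disease_ids = NULL,
                               n_associations = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("association values must be a numeric matrix", call. = FALSE)
  if (nrow(values) < 1 || ncol(values) < 1)
    stop("association matrix needs at least one drug and one disease", call. = FALSE)
  bad <- which(matrix(!(values %in% c(0, 1)), nrow(values)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("association entries must be 0 or 1; first offender at (%d, %d): %g",
                 bad[1, 1], bad[1, 2], values[bad[1, 1], bad[1, 2]]), call. = FALSE)
  ones <- sum(values)
  if (!is.null(n_associations) && ones != n_associations)
    stop(sprintf("declared %d associations but matrix holds %d",
                 n_associations, ones), call. = FALSE)
  if (is.null(drug_ids)) drug_ids <- rownames(values)
  if (is.null(drug_ids)) drug_ids <- paste0("d", seq_len(nrow(values)) - 1L)
  if (is.null(disease_ids)) disease_ids <- colnames(values)
  if (is.null(disease_ids)) disease_ids <- paste0("s", seq_len(ncol(values)) - 1L)
  stopifnot(length(drug_ids) == nrow(values),
            length(disease_ids) == ncol(values))
  storage.mode(values) <- "double"
  dimnames(values) <- list(drug_ids, disease_ids)
  structure(values, class = c("drf_association", "matrix", "array"))
}

#' Summary statistics of an association matrix
#'
#' Counts and sparsity in the layout of the standard benchmark tables:
#' number of drugs, diseases and known associations, and the association
#' density `n_associations / (n_drugs * n_diseases)` (kept at full precision;
#' benchmark tables print it rounded to 4 decimals).
#'
#' @param assoc a `drf_association` (or plain binary matrix).
#' @return one-row tibble with columns `n_drugs`, `n_diseases`,
#'   `n_associations`, `sparsity`.
#' @export
#' @examples
#' dataset_summary(association_matrix(matrix(c(1, 0, 1, 1, 0, 0), nrow = 3)))
dataset_summary <- function(assoc) {
  if (!inherits(assoc, "drf_association")) assoc <- association_matrix(assoc)
  tibble::tibble(
    n_drugs = nrow(assoc),
    n_diseases = ncol(assoc),
    n_associations = as.integer(sum(assoc)),
    sparsity = sum(assoc) / (nrow(assoc) * ncol(assoc))
  )
}

#' @export
print.drf_similarity <- function(x, ...) {
  cat(sprintf("<similarity matrix: %d %ss>\n", nrow(x), attr(x, "entity_kind")))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  invisible(x)
}

#' @export
print.drf_association <- function(x, ...) {
  cat(sprintf("<association matrix: %d drugs x %d diseases, %d known associations>\n",
              nrow(x), ncol(x), as.integer(sum(x))))
  invisible(x)
}
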