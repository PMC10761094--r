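# File formats: dense TSV/CSV (optional header row + index column) and
# MatrixMarket (MTX) via the Matrix package. Orientation is drugs = rows,
# diseases = columns; `transpose = TRUE` flips an input stored the other way.

guess_format <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
         stop(sprintf("cannot guess format from extension '.%s'; pass format=", ext),
              call. = FALSE))
}

read_dense_matrix <- function(path, delim) {
  first <- readLines(path, n = 1L)
  cells <- strsplit(first, delim, fixed = TRUE)[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(cells[-1]))))
  df <- readr::read_delim(path, delim = delim,
                          col_names = has_header,
                          show_col_types = FALSE, progress = FALSE,
                          name_repair = "unique_quiet")
  rn <- NULL
  first_col <- df[[1]]
  if (is.character(first_col)) {
    rn <- first_col
    df <- df[, -1, drop = FALSE]
  }
  non_num <- !vapply(df, is.numeric, logical(1))
  if (any(non_num))
    stop(sprintf("non-numeric column %d in %s", which(non_num)[1], path),
         call. = FALSE)
  m <- as.matrix(df)
  rownames(m) <- rn
  if (!has_header) colnames(m) <- NULL
  m
}

read_any_matrix <- function(path, format) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  switch(format,
         tsv = read_dense_matrix(path, "\t"),
         csv = read_dense_matrix(path, ","),
         mtx = {
           m <- as.matrix(Matrix::readMM(path))
           storage.mode(m) <- "double"  # pattern MTX reads as logical
           m
         })
}

#' Load a drug-disease association matrix from file
#'
#' @param path file path (dense TSV/CSV, or sparse MatrixMarket `.mtx`).
#' @param format `"auto"` (from extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @param transpose set `TRUE` when the file stores diseases as rows.
#' @param n_associations optional declared count, validated after load.
#' @return a [association_matrix()] object.
#' @export
load_association_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                                    transpose = FALSE, n_associations = NULL) {
  m <- read_any_matrix(path, guess_format(path, format))
  if (transpose) m <- t(m)
  association_matrix(m, n_associations = n_associations)
}

#' Load a similarity matrix from file
#'
#' @inheritParams load_association_matrix
#' @param entity_kind `"drug"` or `"disease"`.
#' @param tol symmetry tolerance passed to [similarity_matrix()].
#' @return a [similarity_matrix()] object.
#' @export
load_similarity_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                                   entity_kind = c("drug", "disease"),
                                   transpose = FALSE, tol = 1e-8) {
  m <- read_any_matrix(path, guess_format(path, format))
  if (transpose) m <- t(m)
  similarity_matrix(m, entity_kind = match.arg(entity_kind), tol = tol)
}

#' Write a matrix to TSV/CSV/MTX
#'
#' Dense writes keep full precision (up to 17 significant digits) so a
#' write-read round trip reproduces real entries within 1e-12 and integer
#' content bit-exactly.
#'
#' @param m matrix to write (association or similarity containers accepted).
#' @param path destination; format guessed from extension unless given.
#' @param format `"auto"`, `"tsv"`, `"csv"` or `"mtx"`.
#' @param labels include dimnames as header row / index column (dense only).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("auto", "tsv", "csv", "mtx"),
                         labels = !is.null(rownames(m))) {
  format <- guess_format(path, format)
  m <- unclass(m)
  if (format == "mtx") {
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    return(invisible(path))
  }
  delim <- if (format == "tsv") "\t" else ","
  fm <- matrix(format(m, digits = 17, trim = TRUE, scientific = FALSE),
               nrow = nrow(m), dimnames = dimnames(m))
  if (labels && !is.null(rownames(m))) {
    utils::write.table(fm, path, sep = delim, quote = FALSE, col.names = NA)
  } else {
    utils::write.table(fm, path, sep = delim, quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset directory
#'
#' The directory convention is `assoc.{tsv|csv|mtx}`, `drug_sim.tsv`,
#' `disease_sim.tsv` and an optional `meta.yaml` (fields `n_associations`,
#' `name`).
#'
#' @param dir dataset directory.
#' @return list with elements `assoc`, `drug_sim`, `disease_sim`, `meta`.
#' @export
read_dataset_dir <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("no such dataset directory: %s", dir), call. = FALSE)
  assoc_path <- Filter(file.exists,
                       file.path(dir, c("assoc.tsv", "assoc.csv", "assoc.mtx")))
  if (length(assoc_path) == 0)
    stop("dataset directory has no assoc.{tsv|csv|mtx}", call. = FALSE)
  meta <- list()
  meta_path <- file.path(dir, "meta.yaml")
  if (file.exists(meta_path)) meta <- yaml::read_yaml(meta_path)
  list(
    assoc = load_association_matrix(assoc_path[[1]],
                                    n_associations = meta$n_associations),
    drug_sim = load_similarity_matrix(file.path(dir, "drug_sim.tsv"), "tsv", "drug"),
    disease_sim = load_similarity_matrix(file.path(dir, "disease_sim.tsv"), "tsv", "disease"),
    meta = meta
  )
}

#' Write a dataset directory
#'
#' @param assoc association matrix.
#' @param drug_sim,disease_sim similarity matrices.
#' @param dir destination directory (created if needed).
#' @param sparse write the association matrix as MTX instead of TSV.
#' @return `dir`, invisibly.
#' @export
write_dataset_dir <- function(assoc, drug_sim, disease_sim, dir, sparse = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix(assoc, file.path(dir, if (sparse) "assoc.mtx" else "assoc.tsv"))
  write_matrix(drug_sim, file.path(dir, "drug_sim.tsv"))
  write_matrix(disease_sim, file.path(dir, "disease_sim.tsv"))
  yaml::write_yaml(list(n_associations = as.integer(sum(assoc))),
                   file.path(dir, "meta.yaml"))
  invisible(dir)
}
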