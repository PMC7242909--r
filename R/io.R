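#' Write an expression matrix as MatrixMarket MTX with TSV sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv` and `cells.tsv` into `dir` (created if
#' needed), the exchange layout used throughout single-cell tooling.
#'
#' @param matrix genes x cells matrix.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_matrix_mtx <- function(matrix, dir) {
  check_matrix(matrix, require_nonneg = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(matrix, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(matrix), file.path(dir, "genes.tsv"))
  writeLines(colnames(matrix), file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' Read an expression matrix from MatrixMarket MTX with TSV sidecars
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`, `cells.tsv`.
#' @return dense genes x cells matrix with dimnames.
#' @export
read_matrix_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "cells.tsv"))
  m
}

#' Write / read a dense TSV expression matrix
#'
#' Genes as rows, cells as columns, first column holding gene names.
#' @param matrix genes x cells matrix.
#' @param path file path.
#' @export
write_matrix_tsv <- function(matrix, path) {
  check_matrix(matrix, require_nonneg = FALSE)
  df <- data.frame(gene = rownames(matrix), matrix, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @importFrom methods as
NULL
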