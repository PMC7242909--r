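#' Quality-control thresholds
#'
#' Defaults follow plate-based Smart-seq2 practice: a cell must detect at
#' least 1500 genes and carry at most 20% mitochondrial expression; a gene
#' must be expressed in at least 3 surviving cells. All comparisons are
#' strict on the failing side: a cell with exactly 1500 detected genes or
#' exactly 20% mitochondrial share is retained, and a gene expressed in
#' exactly 3 cells is kept.
#'
#' @param min_detected_genes minimum detected (expression > 0) genes per cell.
#' @param max_mito_fraction maximum mitochondrial share of a cell's total.
#' @param min_cells_per_gene minimum expressing cells per gene.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_detected_genes = 1500, max_mito_fraction = 0.20,
                          min_cells_per_gene = 3) {
  if (min_detected_genes < 0) stop("'min_detected_genes' must be >= 0")
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("'max_mito_fraction' must lie in [0, 1]")
  }
  structure(list(min_detected_genes = min_detected_genes,
                 max_mito_fraction = max_mito_fraction,
                 min_cells_per_gene = min_cells_per_gene),
            class = "qc_thresholds")
}

#' Per-cell quality-control metrics
#'
#' Computed on the TPM scale as delivered by quantification, before spike-in
#' removal: detected genes (expression strictly above zero), mitochondrial
#' fraction (sum over `mito_prefix` rows divided by the cell total; 0 for an
#' all-zero cell) and the cell's expression total.
#'
#' @param matrix genes x cells non-negative matrix.
#' @param mito_prefix row-name prefix identifying mitochondrial genes.
#' @return data.frame with one row per cell: `cell`, `detected_genes`,
#'   `mito_fraction`, `total_tpm`.
#' @export
compute_qc_metrics <- function(matrix, mito_prefix = "mt-") {
  check_matrix(matrix)
  mito_rows <- grep(paste0("^", mito_prefix), rownames(matrix))
  if (length(mito_rows) == 0) {
    warning("no '", mito_prefix, "' rows found; mito_fraction is 0 for all cells")
  }
  total <- colSums(matrix)
  mito <- if (length(mito_rows)) colSums(matrix[mito_rows, , drop = FALSE])
          else rep(0, ncol(matrix))
  frac <- ifelse(total > 0, mito / total, 0)
  data.frame(cell = colnames(matrix),
             detected_genes = colSums(matrix > 0),
             mito_fraction = frac,
             total_tpm = total,
             row.names = colnames(matrix))
}

#' Remove low-quality cells
#'
#' Drops cells with fewer detected genes than `min_detected_genes` or a
#' mitochondrial fraction strictly above `max_mito_fraction` (both boundaries
#' retain the cell). The default combines the two conditions with OR, the
#' universal practice; `combine = "and"` restores a literal conjunction in
#' which a cell must fail both to be removed.
#'
#' @param matrix genes x cells matrix.
#' @param metrics output of [compute_qc_metrics()] for the same cells.
#' @param thresholds a [qc_thresholds()].
#' @param combine "or" (default) or "and".
#' @return The matrix restricted to surviving cells, column order preserved.
#' @export
filter_cells <- function(matrix, metrics, thresholds = qc_thresholds(),
                         combine = c("or", "and")) {
  combine <- match.arg(combine)
  check_matrix(matrix)
  if (!all(colnames(matrix) %in% metrics$cell)) {
    stop("metrics do not cover all cells in the matrix")
  }
  metrics <- metrics[match(colnames(matrix), metrics$cell), ]
  low_genes <- metrics$detected_genes < thresholds$min_detected_genes
  high_mito <- metrics$mito_fraction > thresholds$max_mito_fraction
  fail <- if (combine == "or") low_genes | high_mito else low_genes & high_mito
  if (all(fail)) {
    stop(sprintf(
      "all cells removed by QC (min_detected_genes=%d, max_mito_fraction=%g)",
      thresholds$min_detected_genes, thresholds$max_mito_fraction))
  }
  matrix[, !fail, drop = FALSE]
}

#' Remove rarely expressed genes
#'
#' A gene is retained iff it is expressed (value > 0) in at least
#' `min_cells_per_gene` cells; applied after cell filtering.
#'
#' @inheritParams filter_cells
#' @param min_cells_per_gene minimum expressing cells.
#' @return The matrix restricted to surviving genes.
#' @export
filter_genes <- function(matrix, min_cells_per_gene = 3) {
  check_matrix(matrix)
  keep <- rowSums(matrix > 0) >= min_cells_per_gene
  matrix[keep, , drop = FALSE]
}

#' Drop spike-in rows and renormalize to endogenous TPM
#'
#' Removes ERCC spike-in rows (detected by name prefix) and rescales each
#' remaining column to sum to one million, so downstream values are
#' endogenous TPM. All-zero cells stay all-zero. Within-cell proportions
#' among endogenous genes are unchanged.
#'
#' @param matrix genes x cells TPM matrix.
#' @param ercc_prefix row-name prefix identifying spike-in rows.
#' @return The renormalized endogenous matrix.
#' @export
strip_spikeins_rescale <- function(matrix, ercc_prefix = "ERCC-") {
  check_matrix(matrix)
  ercc_rows <- grep(paste0("^", ercc_prefix), rownames(matrix))
  if (length(ercc_rows)) matrix <- matrix[-ercc_rows, , drop = FALSE]
  rescale_columns(matrix)
}

#' Log-transform an expression matrix
#'
#' Elementwise natural log(x + 1); the scale used by every downstream stage
#' and by the package's reported means.
#'
#' @param matrix non-negative matrix.
#' @param base logarithm base (default natural).
#' @return log-transformed matrix.
#' @export
log_transform <- function(matrix, base = exp(1)) {
  check_matrix(matrix)
  log1p(matrix) / log(base)
}
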