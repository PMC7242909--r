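#' Expression-matched module score
#'
#' Scores each cell for a gene set as the set's mean expression minus the
#' mean of control genes drawn to match the set's expression profile: genes
#' are binned by average expression across all cells into `n_bins`
#' equal-frequency bins, and for every set gene `n_controls_per_gene`
#' controls are sampled (without replacement where the bin allows) from the
#' same bin. Scores therefore center on zero for a set that behaves like the
#' background.
#'
#' @param matrix log-transformed genes x cells matrix.
#' @param genes the gene set; silently intersected with the matrix genes,
#'   error if the intersection is empty.
#' @param n_bins expression bins for control matching (default 24).
#' @param n_controls_per_gene controls sampled per set gene (default 100).
#' @param seed RNG seed for control sampling.
#' @return named per-cell numeric score.
#' @export
module_score <- function(matrix, genes, n_bins = 24,
                         n_controls_per_gene = 100, seed = 0) {
  check_matrix(matrix, require_nonneg = FALSE)
  genes <- intersect(genes, rownames(matrix))
  if (length(genes) == 0) stop("gene set does not intersect matrix genes")
  avg <- rowMeans(matrix)
  n_bins <- min(n_bins, nrow(matrix))
  bin <- ceiling(rank(avg, ties.method = "first") * n_bins / nrow(matrix))
  names(bin) <- rownames(matrix)
  set.seed(seed)
  controls <- unlist(lapply(genes, function(g) {
    pool <- names(bin)[bin == bin[g]]
    sample(pool, min(n_controls_per_gene, length(pool)))
  }))
  set_mean <- colMeans(matrix[genes, , drop = FALSE])
  ctrl_mean <- colMeans(matrix[controls, , drop = FALSE])
  set_mean - ctrl_mean
}

#' Regress a per-cell covariate out of every gene
#'
#' Replaces each gene's expression with the residuals of an ordinary
#' least-squares fit on the covariate, with the gene's mean added back
#' (intercept retained). Residuals are exactly uncorrelated with the
#' covariate. A constant covariate leaves the matrix unchanged with a
#' warning.
#'
#' @param matrix genes x cells matrix.
#' @param covariate finite numeric vector, one value per cell (e.g. a cell
#'   cycle score).
#' @return matrix of the same shape.
#' @export
regress_out <- function(matrix, covariate) {
  check_matrix(matrix, require_nonneg = FALSE)
  if (length(covariate) != ncol(matrix)) {
    stop("covariate length must equal the number of cells")
  }
  if (!all(is.finite(covariate))) stop("covariate must be finite")
  cc <- covariate - mean(covariate)
  ss <- sum(cc^2)
  if (ss < .Machine$double.eps) {
    warning("constant covariate; matrix returned unchanged")
    return(matrix)
  }
  beta <- as.vector(matrix %*% cc) / ss
  matrix - outer(beta, cc)
}

#' Read marker gene pairs for cell-cycle scoring
#'
#' CSV with columns `phase`, `first`, `second`; one ordered gene pair per
#' row. Pairs encode "first gene above second gene" relations characteristic
#' of a cycle phase.
#'
#' @param path CSV file path.
#' @return named list of data.frames (columns `first`, `second`), one per
#'   phase.
#' @export
read_marker_pairs <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("phase", "first", "second")
  if (!all(need %in% names(df))) {
    stop("marker-pair CSV must have columns phase, first, second")
  }
  if (any(df$first == df$second)) stop("pair with identical genes")
  split(df[c("first", "second")], df$phase)
}

#' Pair-based cell-cycle score
#'
#' For each cell, the proportion of usable marker pairs whose first gene is
#' expressed strictly above the second; ties (including the all-zero cell)
#' count as not greater. Pairs are usable when both genes are present in the
#' matrix; at least one is required.
#'
#' @param matrix genes x cells matrix (any monotone scale).
#' @param pairs data.frame with columns `first` and `second`.
#' @return named per-cell score in [0, 1].
#' @export
cell_cycle_score <- function(matrix, pairs) {
  check_matrix(matrix, require_nonneg = FALSE)
  if (any(pairs$first == pairs$second)) stop("pair with identical genes")
  usable <- pairs$first %in% rownames(matrix) &
    pairs$second %in% rownames(matrix)
  if (!any(usable)) stop("no usable marker pairs for this matrix")
  pairs <- pairs[usable, , drop = FALSE]
  gt <- matrix[pairs$first, , drop = FALSE] >
    matrix[pairs$second, , drop = FALSE]
  colMeans(gt)
}

#' Assign a cell-cycle phase from per-phase scores
#'
#' A phase qualifies when its score exceeds 0.5; a cell is labeled with the
#' highest-scoring qualifying phase. Cells with no qualifying phase, or a tie
#' at the top, are labeled "unassigned".
#'
#' @param scores cells x phases matrix or data.frame of scores in [0, 1]
#'   (e.g. columns G1, S, G2M from [cell_cycle_score()]).
#' @param threshold qualification threshold (default 0.5).
#' @return character vector of phase labels per cell.
#' @export
assign_phase <- function(scores, threshold = 0.5) {
  scores <- as.matrix(scores)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  phases <- colnames(scores)
  if (is.null(phases)) stop("score columns must be named by phase")
  apply(scores, 1, function(s) {
    ok <- s > threshold
    if (!any(ok)) return("unassigned")
    top <- max(s[ok])
    winners <- phases[ok & s == top]
    if (length(winners) != 1) "unassigned" else winners
  })
}
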