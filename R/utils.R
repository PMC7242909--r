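#' @keywords internal
"_PACKAGE"

#' @importFrom stats prcomp pnorm p.adjust quantile var sd rlnorm rbinom predict dist setNames
#' @importFrom utils read.csv write.csv
NULL

# Extract a bare integer label vector (named by cell) from either a
# cluster_assignment object or a plain vector.
as_cluster_labels <- function(assignment) {
  if (inherits(assignment, "cluster_assignment")) {
    return(assignment$cluster)
  }
  if (is.factor(assignment)) {
    labs <- as.character(assignment)
    names(labs) <- names(assignment)
    return(labs)
  }
  assignment
}

check_matrix <- function(matrix, require_nonneg = TRUE) {
  if (!is.matrix(matrix) || !is.numeric(matrix)) {
    stop("expression matrix must be a numeric matrix (genes x cells)")
  }
  if (is.null(rownames(matrix)) || is.null(colnames(matrix))) {
    stop("expression matrix must carry gene rownames and cell colnames")
  }
  if (require_nonneg && any(matrix < 0)) {
    stop("expression matrix must be non-negative")
  }
  invisible(matrix)
}

# Rescale every column to a fixed total (TPM contract); all-zero columns are
# left all-zero.
rescale_columns <- function(matrix, total = 1e6) {
  cs <- colSums(matrix)
  nz <- cs > 0
  matrix[, nz] <- sweep(matrix[, nz, drop = FALSE], 2, cs[nz] / total, "/")
  matrix
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same cells.
#' Returns 1 for identical partitions (up to label names) and has expectation
#' 0 under random labelings with the same margins.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  s_ij <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_index <- (s_a + s_b) / 2
  if (max_index == expected) return(1)
  (s_ij - expected) / (max_index - expected)
}
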