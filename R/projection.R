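#' Fit a multinomial logistic projection model on reference clusters
#'
#' Trains an L2-regularized multinomial logistic classifier (ridge penalty,
#' one weight vector per cluster) on log-normalized reference expression,
#' for projecting external cells onto the reference cluster structure. The
#' penalty is given in the inverse-penalty convention C (larger C, weaker
#' regularization); internally the ridge is fit at lambda = 1 / (n * C).
#'
#' @param matrix log-normalized genes x cells reference matrix.
#' @param assignment cluster labels aligned with columns; at least 2
#'   clusters with >= 3 cells each.
#' @param penalty inverse regularization strength C (default 1).
#' @param genes feature genes (default all); callers comparing against a
#'   known query typically pass the gene intersection here.
#' @param tol optimizer convergence threshold (default 1e-6).
#' @return A `projection_model`: the fitted object plus `genes`, `classes`,
#'   `penalty`, `lambda`.
#' @export
fit_projection <- function(matrix, assignment, penalty = 1.0,
                           genes = rownames(matrix), tol = 1e-6) {
  check_matrix(matrix, require_nonneg = FALSE)
  labels <- as_cluster_labels(assignment)
  if (length(labels) != ncol(matrix)) {
    stop("assignment does not match matrix columns")
  }
  tab <- table(labels)
  if (length(tab) < 2) stop("reference must contain at least 2 clusters")
  if (any(tab < 3)) stop("every reference cluster needs at least 3 cells")
  if (penalty <= 0) stop("'penalty' must be positive")
  genes <- intersect(genes, rownames(matrix))
  if (length(genes) < 2) stop("need at least 2 feature genes")
  x <- t(matrix[genes, , drop = FALSE])
  y <- factor(labels)
  lambda <- 1 / (ncol(matrix) * penalty)
  fit <- glmnet::glmnet(x, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = FALSE, thresh = tol)
  structure(list(fit = fit, genes = genes, classes = levels(y),
                 penalty = penalty, lambda = lambda),
            class = "projection_model")
}

#' Project query cells onto reference clusters
#'
#' Scores each query cell with the model's softmax probabilities over the
#' reference clusters. Model genes missing from the query are imputed as 0
#' (their count is messaged); the query may carry extra genes, which are
#' ignored, and gene order is irrelevant.
#'
#' @param model a [fit_projection()] model.
#' @param query log-normalized genes x cells query matrix sharing at least
#'   one gene with the model.
#' @return cells x clusters probability matrix; rows sum to 1.
#' @export
project_cells <- function(model, query) {
  check_matrix(query, require_nonneg = FALSE)
  shared <- intersect(model$genes, rownames(query))
  if (length(shared) == 0) stop("query shares no genes with the model")
  missing <- setdiff(model$genes, rownames(query))
  if (length(missing) > 0) {
    message(length(missing), " model gene(s) absent from query; imputed as 0")
  }
  xq <- matrix(0, ncol(query), length(model$genes),
               dimnames = list(colnames(query), model$genes))
  xq[, shared] <- t(query[shared, , drop = FALSE])
  probs <- predict(model$fit, newx = xq, type = "response")[, , 1]
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1,
                                           dimnames = list(colnames(query),
                                                           names(probs)))
  probs / rowSums(probs)
}

#' Summarize projection probabilities by query group
#'
#' @param probabilities cells x clusters matrix from [project_cells()].
#' @param groups grouping vector (e.g. query dataset or cell type), one
#'   value per query cell.
#' @return groups x clusters matrix of mean probabilities; rows sum to 1.
#' @export
summarize_projection <- function(probabilities, groups) {
  if (length(groups) != nrow(probabilities)) {
    stop("grouping must cover all query cells")
  }
  sums <- rowsum(probabilities, groups)
  sums / as.vector(table(groups)[rownames(sums)])
}
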