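#' Select highly variable genes
#'
#' Ranks genes by a binned dispersion statistic on the log matrix: genes are
#' grouped into `n_bins` equal-frequency bins of mean expression and the
#' variance of each gene is z-scored within its bin, so variability is judged
#' relative to genes of similar abundance.
#'
#' @param matrix log-transformed genes x cells matrix.
#' @param n_top number of genes to return (clamped to the gene count with a
#'   warning).
#' @param n_bins mean-expression bins (default 20).
#' @return character vector of gene names, most variable first.
#' @export
select_hvg <- function(matrix, n_top = 1000, n_bins = 20) {
  check_matrix(matrix, require_nonneg = FALSE)
  mu <- rowMeans(matrix)
  v <- apply(matrix, 1, var)
  if (all(v < .Machine$double.eps)) stop("no variable genes")
  if (n_top > nrow(matrix)) {
    warning("n_top exceeds gene count; returning all genes")
    n_top <- nrow(matrix)
  }
  n_bins <- min(n_bins, max(1L, floor(nrow(matrix) / 2)))
  bin <- ceiling(rank(mu, ties.method = "first") * n_bins / nrow(matrix))
  z <- v
  for (b in unique(bin)) {
    idx <- bin == b
    s <- sd(v[idx])
    z[idx] <- if (is.na(s) || s < .Machine$double.eps) 0
              else (v[idx] - mean(v[idx])) / s
  }
  rownames(matrix)[order(z, v, decreasing = TRUE)][seq_len(n_top)]
}

#' Embed cells in principal-component space
#'
#' Centers and unit-scales each selected gene across cells, then projects
#' cells onto the top `n_pcs` principal axes. The sign of each component is
#' fixed so that its largest-magnitude gene loading is positive, making the
#' embedding deterministic.
#'
#' @param matrix log-transformed genes x cells matrix.
#' @param genes genes to use (e.g. from [select_hvg()]); default all.
#' @param n_pcs number of components, conventionally 10-30 (default 20);
#'   clamped to the data rank with a warning.
#' @return cells x n_pcs coordinate matrix; gene loadings in
#'   `attr(, "rotation")`, per-component variance in `attr(, "sdev")`.
#' @export
pca_embed <- function(matrix, genes = rownames(matrix), n_pcs = 20) {
  check_matrix(matrix, require_nonneg = FALSE)
  genes <- intersect(genes, rownames(matrix))
  if (length(genes) == 0) stop("no usable genes for the embedding")
  x <- t(matrix[genes, , drop = FALSE])
  sds <- apply(x, 2, sd)
  usable <- sds > .Machine$double.eps
  if (!all(usable)) {
    warning(sum(!usable), " constant gene(s) dropped from the embedding")
    x <- x[, usable, drop = FALSE]
  }
  x <- scale(x)
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_pcs > max_rank) {
    warning("n_pcs exceeds data rank; clamped to ", max_rank)
    n_pcs <- max_rank
  }
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_pcs)
  flip <- apply(pc$rotation, 2, function(w) sign(w[which.max(abs(w))]))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x, 2, flip, "*")
  rownames(scores) <- colnames(matrix)
  attr(scores, "rotation") <- sweep(pc$rotation, 2, flip, "*")
  attr(scores, "sdev") <- pc$sdev[seq_len(n_pcs)]
  scores
}

#' Shared-nearest-neighbor community clustering
#'
#' Builds a k-nearest-neighbor graph on Euclidean distances in the embedding,
#' reweights edges by the Jaccard overlap of the two cells' neighbor sets
#' (pruning weak edges), and partitions the resulting shared-nearest-neighbor
#' graph by modularity-based community detection at the given resolution.
#'
#' @param embedding cells x dims coordinates from [pca_embed()].
#' @param k_neighbors neighbors per cell (default 20).
#' @param resolution modularity resolution; larger values yield more, smaller
#'   communities (default 0.8).
#' @param seed RNG seed for community detection; same seed, same partition.
#' @param prune Jaccard weight below which SNN edges are discarded
#'   (default 1/15).
#' @return A `cluster_assignment`: list with `cluster` (named 0-based integer
#'   ids, contiguous, ordered by decreasing cluster size), plus the
#'   parameters used.
#' @export
cluster_snn <- function(embedding, k_neighbors = 20, resolution = 0.8,
                        seed = 0, prune = 1 / 15) {
  n <- nrow(embedding)
  if (n < k_neighbors + 1) {
    stop("need at least k_neighbors + 1 cells")
  }
  d <- as.matrix(dist(embedding))
  # neighbor sets include the cell itself, so Jaccard is over k+1 elements
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors + 1)]))
  adj <- matrix(0L, n, n)
  adj[cbind(rep(seq_len(n), each = k_neighbors + 1), as.vector(t(nn)))] <- 1L
  shared <- adj %*% t(adj)
  jac <- shared / (2 * (k_neighbors + 1) - shared)
  jac[jac < prune] <- 0
  diag(jac) <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  cluster <- relabel[as.character(memb)]
  names(cluster) <- rownames(embedding)
  structure(list(cluster = cluster, resolution = resolution,
                 n_pcs = ncol(embedding), k_neighbors = k_neighbors,
                 seed = seed),
            class = "cluster_assignment")
}

#' Rank cluster markers by Wilcoxon rank-sum test
#'
#' For every gene, a two-sided Wilcoxon rank-sum test (normal approximation
#' with tie correction) of the cluster's cells against all other cells, with
#' the log fold-change of mean de-logged expression (pseudocount 1) and the
#' expressing-cell fractions inside and outside the cluster. P-values are
#' Bonferroni-adjusted over genes by default.
#'
#' @param matrix log-transformed genes x cells matrix.
#' @param assignment a `cluster_assignment` or bare label vector aligned with
#'   the matrix columns.
#' @param cluster the cluster id to characterize (needs >= 3 cells).
#' @param adjust multiple-testing method: "bonferroni" (default) or "BH".
#' @return data.frame sorted by p-value then |lfc|: `gene`, `cluster`, `lfc`,
#'   `pct_in`, `pct_out`, `statistic` (rank-sum U of the in-group), `p`,
#'   `p_adj`.
#' @export
rank_markers_wilcoxon <- function(matrix, assignment, cluster,
                                  adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  check_matrix(matrix, require_nonneg = FALSE)
  labels <- as_cluster_labels(assignment)
  if (length(labels) != ncol(matrix)) {
    stop("assignment does not match matrix columns")
  }
  in_group <- labels == cluster
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  if (n1 < 3) stop("cluster must have at least 3 cells")

  stats_one <- function(x) {
    r <- rank(x)
    u1 <- sum(r[in_group]) - n1 * (n1 + 1) / 2
    ties <- table(x)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    if (sigma2 <= 0) return(c(u1, 1))
    z <- (u1 - n1 * n2 / 2) / sqrt(sigma2)
    c(u1, 2 * pnorm(-abs(z)))
  }
  res <- t(apply(matrix, 1, stats_one))

  mean_in <- rowMeans(expm1(matrix[, in_group, drop = FALSE]))
  mean_out <- rowMeans(expm1(matrix[, !in_group, drop = FALSE]))
  out <- data.frame(
    gene = rownames(matrix),
    cluster = cluster,
    lfc = log((mean_in + 1) / (mean_out + 1)),
    pct_in = rowMeans(matrix[, in_group, drop = FALSE] > 0),
    pct_out = rowMeans(matrix[, !in_group, drop = FALSE] > 0),
    statistic = res[, 1],
    p = res[, 2],
    row.names = NULL
  )
  out$p_adj <- pmin(p.adjust(out$p, method = adjust), 1)
  out[order(out$p, -abs(out$lfc)), ]
}
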