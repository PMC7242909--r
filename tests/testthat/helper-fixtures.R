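# Shared fixtures, all built in code at test time.

# 6-cell worked toy: ligand on in cluster 0, receptor on in cluster 1.
# Only the observed labeling attains the maximal statistic, so the exact
# permutation p-value over the 20 distinct label assignments is 1/20.
toy6 <- function() {
  mat <- rbind(L1 = c(9, 9, 9, 0, 0, 0),
               R1 = c(0, 0, 0, 9, 9, 9))
  colnames(mat) <- paste0("c", 1:6)
  labels <- stats::setNames(c(0, 0, 0, 1, 1, 1), colnames(mat))
  list(matrix = mat, labels = labels, record = lr_record("I1", "L1", "R1"))
}

# Small, fast simulation for structural tests (cached per options set).
local_sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 1, ...) {
  key <- paste(seed, deparse(list(...)), collapse = "|")
  if (is.null(local_sim_cache[[key]])) {
    cfg <- sim_config(seed = seed, n_clusters = 3, cells_per_cluster = 20,
                      n_genes = 300, n_marker_genes_per_cluster = 30,
                      n_mito_genes = 5, n_ercc = 10, ...)
    local_sim_cache[[key]] <- simulate_matrix(cfg)
  }
  local_sim_cache[[key]]
}

# A deterministic TPM-like toy matrix with named genes/cells.
toy_matrix <- function(values, genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  if (!is.null(genes)) rownames(m) <- genes
  if (!is.null(cells)) colnames(m) <- cells
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  m
}

# Binomial 99% CI half-width for a sampled proportion.
binom99_halfwidth <- function(p, n) stats::qnorm(0.995) * sqrt(p * (1 - p) / n) + 1 / n
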