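#' Simulation configuration
#'
#' Describes a synthetic Smart-seq2-style TPM experiment: a set of clusters of
#' equal size, endogenous genes with a heavy-tailed (log-normal) baseline,
#' cluster-specific marker genes up-shifted by a fold factor, mitochondrial
#' genes and ERCC spike-in rows recognizable by name prefix, Bernoulli
#' dropout, and optionally planted ligand-receptor co-expression signals
#' between cluster pairs.
#'
#' Default magnitudes emulate a plate-based tumor/lymph-node microenvironment
#' dataset at desk scale: 4 clusters of 50 cells, 2000 endogenous genes of
#' which 10% per cluster are markers at fold 8 (distinct cell types differ in
#' 10-20% of expressed genes), 10 mitochondrial genes contributing roughly
#' 5-10% of a cell's TPM, 20 spike-in rows, and a dropout rate of 0.3.
#'
#' @param n_clusters number of cell clusters.
#' @param cells_per_cluster cells per cluster.
#' @param n_genes endogenous (non-mito, non-spike-in) genes.
#' @param n_marker_genes_per_cluster markers planted per cluster; the first
#'   `n_clusters * n_marker_genes_per_cluster` endogenous genes are used.
#' @param n_mito_genes mitochondrial genes (named with `mito_prefix`).
#' @param n_ercc spike-in rows (named with `ercc_prefix`).
#' @param dropout_rate per gene-cell Bernoulli zeroing probability, applied to
#'   endogenous and mitochondrial genes (spike-ins are present in every cell).
#' @param marker_fold fold-change of a marker's mean in its own cluster.
#' @param lr_signals list of planted signals, each a list with elements
#'   `ligand`, `receptor` (gene or "A+B" complex string), `source`, `target`
#'   (0-based cluster ids) and `fold`.
#' @param seed integer RNG seed; the full generator is deterministic given it.
#' @param meanlog,sdlog_gene log-normal parameters for per-gene baseline mean
#'   TPM (before renormalization).
#' @param sdlog_cell log-normal cell-to-cell noise around the gene mean.
#' @param mito_mean_factor,ercc_mean_factor mean multipliers for mito /
#'   spike-in rows (both gene classes are strongly expressed in real data).
#' @param mito_prefix,ercc_prefix row-name prefixes used downstream to detect
#'   the two special gene classes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_clusters = 4, cells_per_cluster = 50, n_genes = 2000,
                       n_marker_genes_per_cluster = 200, n_mito_genes = 10,
                       n_ercc = 20, dropout_rate = 0.3, marker_fold = 8,
                       lr_signals = list(), seed = 1,
                       meanlog = log(20), sdlog_gene = 1, sdlog_cell = 0.5,
                       mito_mean_factor = 20, ercc_mean_factor = 5,
                       mito_prefix = "mt-", ercc_prefix = "ERCC-") {
  cfg <- list(n_clusters = n_clusters, cells_per_cluster = cells_per_cluster,
              n_genes = n_genes,
              n_marker_genes_per_cluster = n_marker_genes_per_cluster,
              n_mito_genes = n_mito_genes, n_ercc = n_ercc,
              dropout_rate = dropout_rate, marker_fold = marker_fold,
              lr_signals = lr_signals, seed = seed,
              meanlog = meanlog, sdlog_gene = sdlog_gene,
              sdlog_cell = sdlog_cell,
              mito_mean_factor = mito_mean_factor,
              ercc_mean_factor = ercc_mean_factor,
              mito_prefix = mito_prefix, ercc_prefix = ercc_prefix)
  counts <- c("n_clusters", "cells_per_cluster", "n_genes",
              "n_marker_genes_per_cluster", "n_mito_genes", "n_ercc")
  for (f in counts) {
    if (length(cfg[[f]]) != 1 || cfg[[f]] < 1 || cfg[[f]] != round(cfg[[f]])) {
      stop(sprintf("'%s' must be a positive integer", f))
    }
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("'dropout_rate' must lie in [0, 1)")
  }
  if (cfg$marker_fold <= 1) stop("'marker_fold' must exceed 1")
  if (cfg$n_marker_genes_per_cluster * cfg$n_clusters > cfg$n_genes) {
    stop("marker genes exceed endogenous gene count")
  }
  for (sig in cfg$lr_signals) {
    if (any(c(sig$source, sig$target) >= cfg$n_clusters) ||
        any(c(sig$source, sig$target) < 0)) {
      stop("lr_signal cluster ids must lie in [0, n_clusters)")
    }
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a TPM expression matrix with known structure
#'
#' Draws per-gene baseline means from a log-normal, multiplies each cluster's
#' marker rows by `marker_fold` in that cluster, adds multiplicative
#' log-normal cell noise, applies Bernoulli dropout to non-spike-in entries,
#' rescales every cell to a TPM total of 1e6 and finally plants any requested
#' ligand-receptor signals via [plant_interaction()]. Deterministic given
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @return A list with `matrix` (genes x cells TPM) and `truth`, a `sim_truth`
#'   list carrying `cell_cluster` (named 0-based ids), `marker_genes` (list of
#'   per-cluster marker gene vectors), `planted` (one record per planted
#'   signal) and `low_quality_cells` (empty until [inject_qc_failures()]).
#' @export
simulate_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_cells <- config$n_clusters * config$cells_per_cluster
  gene_names <- c(sprintf("Gene%04d", seq_len(config$n_genes)),
                  sprintf("%sMt%02d", config$mito_prefix,
                          seq_len(config$n_mito_genes)),
                  sprintf("%s%05d", config$ercc_prefix, seq_len(config$n_ercc)))
  n_total <- length(gene_names)
  cell_names <- sprintf("Cell%04d", seq_len(n_cells))
  cluster <- rep(seq_len(config$n_clusters) - 1L,
                 each = config$cells_per_cluster)
  names(cluster) <- cell_names

  mu <- rlnorm(n_total, config$meanlog, config$sdlog_gene)
  mito_rows <- config$n_genes + seq_len(config$n_mito_genes)
  ercc_rows <- config$n_genes + config$n_mito_genes + seq_len(config$n_ercc)
  mu[mito_rows] <- mu[mito_rows] * config$mito_mean_factor
  mu[ercc_rows] <- mu[ercc_rows] * config$ercc_mean_factor

  mean_mat <- matrix(mu, nrow = n_total, ncol = n_cells)
  marker_genes <- vector("list", config$n_clusters)
  names(marker_genes) <- as.character(seq_len(config$n_clusters) - 1L)
  for (k in seq_len(config$n_clusters)) {
    rows <- (k - 1L) * config$n_marker_genes_per_cluster +
      seq_len(config$n_marker_genes_per_cluster)
    marker_genes[[k]] <- gene_names[rows]
    mean_mat[rows, cluster == (k - 1L)] <-
      mean_mat[rows, cluster == (k - 1L)] * config$marker_fold
  }

  mat <- matrix(rlnorm(n_total * n_cells, meanlog = log(mean_mat),
                       sdlog = config$sdlog_cell),
                nrow = n_total, ncol = n_cells,
                dimnames = list(gene_names, cell_names))
  if (config$dropout_rate > 0) {
    endo <- seq_len(config$n_genes + config$n_mito_genes)
    keep <- matrix(rbinom(length(endo) * n_cells, 1,
                          1 - config$dropout_rate),
                   nrow = length(endo))
    mat[endo, ] <- mat[endo, ] * keep
  }
  mat <- rescale_columns(mat)

  truth <- structure(list(cell_cluster = cluster,
                          marker_genes = marker_genes,
                          planted = list(),
                          low_quality_cells = character(0)),
                     class = "sim_truth")
  for (sig in config$lr_signals) {
    res <- plant_interaction(mat, truth, sig$ligand, sig$receptor,
                             sig$source, sig$target, sig$fold)
    mat <- res$matrix
    truth <- res$truth
  }
  list(matrix = mat, truth = truth)
}

# Split an "A+B+C" complex string (or pass through a character vector of
# subunits) into a subunit vector.
parse_partner <- function(partner) {
  if (length(partner) == 1 && grepl("+", partner, fixed = TRUE)) {
    partner <- strsplit(partner, "+", fixed = TRUE)[[1]]
  }
  partner <- trimws(partner)
  if (any(partner == "")) stop("empty subunit in partner specification")
  if (anyDuplicated(partner)) stop("duplicated subunit within a partner")
  partner
}

#' Plant a ligand-receptor co-expression signal between two clusters
#'
#' Up-shifts the ligand partner's gene(s) in the source cluster and the
#' receptor partner's gene(s) (all subunits, for a complex) in the target
#' cluster by `fold`, guarantees each planted gene is detected in more than
#' `detection_threshold` of its cluster's cells (zero entries are backfilled
#' with the gene's positive cluster mean, deterministically in column order),
#' rescales affected cells back to 1e6, and appends the signal to
#' `truth$planted`. A `fold` of exactly 1 leaves the matrix untouched and only
#' records the signal.
#'
#' @param matrix genes x cells TPM matrix.
#' @param truth a `sim_truth` (for cluster labels and the planted registry).
#' @param ligand,receptor gene name or "A+B" complex string.
#' @param source_cluster,target_cluster 0-based cluster ids receiving the
#'   ligand / receptor shift.
#' @param fold multiplicative shift, >= 1.
#' @param detection_threshold expressed-cell fraction each planted gene must
#'   strictly exceed in its cluster (default 0.10, matching the downstream
#'   communication filter).
#' @return list(matrix, truth) with the edit applied and recorded.
#' @export
plant_interaction <- function(matrix, truth, ligand, receptor,
                              source_cluster, target_cluster, fold,
                              detection_threshold = 0.10) {
  check_matrix(matrix)
  lig <- parse_partner(ligand)
  rec <- parse_partner(receptor)
  missing <- setdiff(c(lig, rec), rownames(matrix))
  if (length(missing)) {
    stop("unknown gene(s) in planted interaction: ",
         paste(missing, collapse = ", "))
  }
  labels <- truth$cell_cluster
  for (cl in c(source_cluster, target_cluster)) {
    if (!cl %in% labels) stop("unknown cluster id: ", cl)
  }
  if (fold < 1) stop("'fold' must be >= 1")
  record <- list(id = paste0(paste(lig, collapse = "+"), "_",
                             paste(rec, collapse = "+")),
                 ligand = lig, receptor = rec,
                 source = source_cluster, target = target_cluster,
                 fold = fold)
  truth$planted <- c(truth$planted, list(record))
  if (fold == 1) return(list(matrix = matrix, truth = truth))

  shift <- function(mat, genes, cluster) {
    cells <- names(labels)[labels == cluster]
    for (g in genes) {
      x <- mat[g, cells]
      n_pos <- sum(x > 0)
      need <- floor(detection_threshold * length(cells)) + 1L - n_pos
      if (need > 0) {
        fill <- if (n_pos > 0) mean(x[x > 0]) else
          max(mean(mat[g, mat[g, ] > 0]), 1)
        zero_cells <- cells[x == 0][seq_len(need)]
        mat[g, zero_cells] <- fill
      }
      mat[g, cells] <- mat[g, cells] * fold
    }
    mat[, cells] <- rescale_columns(mat[, cells, drop = FALSE])
    mat
  }
  matrix <- shift(matrix, lig, source_cluster)
  matrix <- shift(matrix, rec, target_cluster)
  list(matrix = matrix, truth = truth)
}

#' Inject cells built to fail quality control
#'
#' Marks `n_low_gene` cells down to fewer detected genes than
#' `thresholds$min_detected_genes` (keeping their most-expressed entries) and
#' inflates the mitochondrial share of `n_high_mito` further cells strictly
#' above `thresholds$max_mito_fraction`; affected columns are rescaled to 1e6
#' and the cell ids recorded in `truth$low_quality_cells`. Victim cells are
#' sampled with the current RNG; callers wanting determinism set a seed.
#'
#' @param matrix genes x cells TPM matrix.
#' @param truth a `sim_truth`.
#' @param n_low_gene,n_high_mito number of cells to degrade each way.
#' @param thresholds a [qc_thresholds()] the failures are defined against.
#' @param mito_prefix prefix of mitochondrial rows.
#' @param target_mito_fraction mito share given to high-mito cells (must
#'   exceed the threshold; default 0.5).
#' @return list(matrix, truth).
#' @export
inject_qc_failures <- function(matrix, truth, n_low_gene, n_high_mito,
                               thresholds = qc_thresholds(),
                               mito_prefix = "mt-",
                               target_mito_fraction = 0.5) {
  check_matrix(matrix)
  if (n_low_gene + n_high_mito > ncol(matrix)) {
    stop("more QC failures requested than cells available")
  }
  if (n_low_gene == 0 && n_high_mito == 0) {
    return(list(matrix = matrix, truth = truth))
  }
  mito_rows <- grep(paste0("^", mito_prefix), rownames(matrix))
  if (n_high_mito > 0 && length(mito_rows) == 0) {
    stop("matrix has no '", mito_prefix, "' rows; cannot inject high-mito cells")
  }
  if (n_high_mito > 0 && target_mito_fraction <= thresholds$max_mito_fraction) {
    stop("'target_mito_fraction' must exceed the mito threshold")
  }
  victims <- sample(colnames(matrix), n_low_gene + n_high_mito)
  low <- victims[seq_len(n_low_gene)]
  high <- victims[n_low_gene + seq_len(n_high_mito)]

  keep_n <- max(1L, floor(thresholds$min_detected_genes / 2))
  for (cell in low) {
    x <- matrix[, cell]
    keep <- order(x, decreasing = TRUE)[seq_len(min(keep_n, sum(x > 0)))]
    x[-keep] <- 0
    matrix[, cell] <- x
  }
  for (cell in high) {
    m <- sum(matrix[mito_rows, cell])
    if (m == 0) {
      matrix[mito_rows, cell] <- 1
      m <- length(mito_rows)
    }
    e <- sum(matrix[-mito_rows, cell])
    t <- target_mito_fraction * e / ((1 - target_mito_fraction) * m)
    matrix[mito_rows, cell] <- matrix[mito_rows, cell] * t
  }
  matrix[, victims] <- rescale_columns(matrix[, victims, drop = FALSE])
  truth$low_quality_cells <- union(truth$low_quality_cells, victims)
  list(matrix = matrix, truth = truth)
}

#' Simulate a communication benchmark with planted and decoy interactions
#'
#' Builds the standard fixture for evaluating the permutation test: a
#' clustered TPM matrix in which `n_signals` ligand-receptor signals are
#' planted on consecutive cluster pairs (0 to 1, 1 to 2, ...), the second
#' signal carrying a 2-subunit complex receptor, together with `n_decoys`
#' interactions on unperturbed genes. Interaction genes are drawn from the
#' low-abundance band of the baseline transcriptome (5th-30th percentile of
#' mean TPM among non-marker genes), emulating the modest expression typical
#' of cytokines and their receptors.
#'
#' @param seed integer seed driving the whole construction.
#' @param n_signals planted signals (at most `n_clusters` of the config).
#' @param fold planted fold-change (default 8).
#' @param n_decoys decoy interactions on untouched genes.
#' @param config base [sim_config()]; its `lr_signals` are overwritten.
#' @return list with `matrix` (TPM), `truth`, `db` (an `lr_db` of planted
#'   then decoy records, ids "P1...", "D1..."), and `planted` (data.frame of
#'   interaction id, source, target).
#' @export
simulate_communication_benchmark <- function(seed = 1, n_signals = 3,
                                             fold = 8, n_decoys = 10,
                                             config = sim_config(seed = seed)) {
  if (n_signals > config$n_clusters) stop("more signals than cluster pairs")
  base <- simulate_matrix(config)
  nonmark <- setdiff(rownames(base$matrix)[seq_len(config$n_genes)],
                     unlist(base$truth$marker_genes))
  mu <- rowMeans(base$matrix[nonmark, ])
  band <- quantile(mu, c(0.05, 0.30))
  pool <- nonmark[mu > band[1] & mu < band[2]]
  set.seed(seed + 90000L)
  genes <- sample(pool, 3 * n_signals + 2 * n_decoys)
  gi <- 0L
  take <- function(k) { idx <- gi + seq_len(k); gi <<- gi + k; genes[idx] }
  sigs <- vector("list", n_signals)
  for (i in seq_len(n_signals)) {
    lig <- take(1)
    rec <- if (i == 2) paste(take(2), collapse = "+") else take(1)
    sigs[[i]] <- list(ligand = lig, receptor = rec,
                      source = (i - 1L) %% config$n_clusters,
                      target = i %% config$n_clusters, fold = fold)
  }
  config$lr_signals <- sigs
  sim <- simulate_matrix(config)
  db <- c(lapply(seq_len(n_signals), function(i) {
    lr_record(paste0("P", i), sigs[[i]]$ligand, sigs[[i]]$receptor)
  }), lapply(seq_len(n_decoys), function(i) {
    lr_record(paste0("D", i), take(1), take(1))
  }))
  planted <- data.frame(
    interaction = paste0("P", seq_len(n_signals)),
    source = vapply(sigs, `[[`, numeric(1), "source"),
    target = vapply(sigs, `[[`, numeric(1), "target"))
  list(matrix = sim$matrix, truth = sim$truth,
       db = structure(db, class = "lr_db"), planted = planted)
}
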