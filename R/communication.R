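#' Construct a ligand-receptor interaction record
#'
#' A partner is a single gene or a heteromeric complex given as an ordered
#' set of subunit genes ("A+B+C" string or character vector). By convention
#' `partner_a` is the ligand and `partner_b` the receptor.
#'
#' @param id unique interaction identifier.
#' @param partner_a,partner_b gene or complex specification.
#' @param annotation optional free-text annotation.
#' @return An `lr_record` list.
#' @export
lr_record <- function(id, partner_a, partner_b, annotation = NA_character_) {
  structure(list(id = id,
                 partner_a = parse_partner(partner_a),
                 partner_b = parse_partner(partner_b),
                 annotation = annotation),
            class = "lr_record")
}

#' Load a ligand-receptor interaction database from CSV
#'
#' Expected columns: `id,partner_a,partner_b` with complexes written as
#' `GENE1+GENE2+...`; an optional `annotation` column is carried through.
#' Duplicate ids and malformed rows are rejected with the offending line
#' number.
#'
#' @param path CSV file path.
#' @return list of [lr_record()]s, class `lr_db`.
#' @export
load_interaction_db <- function(path) {
  if (!file.exists(path)) stop("interaction database not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "partner_a", "partner_b")
  if (!all(need %in% names(df))) {
    stop("interaction CSV must have columns id, partner_a, partner_b")
  }
  records <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    ok <- tryCatch({
      if (is.na(row$id) || row$id == "") stop("missing id")
      records[[i]] <- lr_record(
        row$id, row$partner_a, row$partner_b,
        if ("annotation" %in% names(df)) row$annotation else NA_character_)
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) {
      stop(sprintf("malformed interaction row at line %d: %s",
                   i + 1L, conditionMessage(ok)))
    }
  }
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("duplicate interaction id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(records, class = "lr_db")
}

# Per-cluster mean expression and expressing-cell fraction for every gene.
cluster_profile <- function(matrix, labels) {
  clusters <- sort(unique(labels))
  ind <- matrix(0, ncol(matrix), length(clusters),
                dimnames = list(colnames(matrix), as.character(clusters)))
  ind[cbind(seq_along(labels), match(labels, clusters))] <- 1
  sizes <- colSums(ind)
  list(mean = sweep(matrix %*% ind, 2, sizes, "/"),
       frac = sweep((matrix > 0) %*% ind, 2, sizes, "/"),
       clusters = clusters, sizes = sizes, indicator = ind)
}

#' Fraction of a cluster's cells expressing a gene
#'
#' @param matrix genes x cells matrix.
#' @param assignment cluster labels (object or vector) aligned with columns.
#' @param cluster cluster id.
#' @param gene gene name.
#' @return proportion in [0, 1] of the cluster's cells with expression > 0.
#' @export
expressed_fraction <- function(matrix, assignment, cluster, gene) {
  check_matrix(matrix, require_nonneg = FALSE)
  labels <- as_cluster_labels(assignment)
  if (!gene %in% rownames(matrix)) stop("unknown gene: ", gene)
  cells <- labels == cluster
  if (!any(cells)) stop("cluster has no cells: ", cluster)
  mean(matrix[gene, cells] > 0)
}

#' Score one interaction partner in one cluster
#'
#' A simple partner qualifies when its expressing-cell fraction in the
#' cluster strictly exceeds `threshold`; its mean is the gene's cluster
#' average and the effective gene is itself. A heteromeric complex qualifies
#' only when every subunit passes the fraction filter; its effective gene is
#' the subunit with the minimum cluster-average expression, whose average
#' becomes the partner mean.
#'
#' @inheritParams expressed_fraction
#' @param partner gene or complex (vector or "A+B" string).
#' @param threshold expression-fraction filter (default 0.10, strict).
#' @return list with `mean`, `qualifies`, `effective_gene`.
#' @export
partner_mean <- function(matrix, assignment, cluster, partner,
                         threshold = 0.10) {
  check_matrix(matrix, require_nonneg = FALSE)
  labels <- as_cluster_labels(assignment)
  partner <- parse_partner(partner)
  missing <- setdiff(partner, rownames(matrix))
  if (length(missing)) stop("unknown gene(s): ", paste(missing, collapse = ", "))
  cells <- labels == cluster
  if (!any(cells)) stop("cluster has no cells: ", cluster)
  sub <- matrix[partner, cells, drop = FALSE]
  means <- rowMeans(sub)
  fracs <- rowMeans(sub > 0)
  eff <- partner[which.min(means)]
  list(mean = unname(means[which.min(means)]),
       qualifies = all(fracs > threshold),
       effective_gene = eff)
}

#' Observed interaction statistic for one cluster pair
#'
#' The statistic is the arithmetic mean of partner_a's average expression in
#' `cluster_a` and partner_b's average expression in `cluster_b`, each taken
#' through the partner's effective gene. The pair is `tested` only when both
#' partners pass the expression-fraction filter in their respective clusters.
#'
#' @inheritParams partner_mean
#' @param cluster_a,cluster_b source (ligand) and target (receptor) clusters;
#'   may coincide (autocrine).
#' @param record an [lr_record()].
#' @return one-row data.frame: `cluster_a`, `cluster_b`, `interaction`,
#'   `effective_a`, `effective_b`, `mean`, `tested`, `autocrine`.
#' @export
observed_interaction_mean <- function(matrix, assignment, cluster_a,
                                      cluster_b, record, threshold = 0.10) {
  pa <- partner_mean(matrix, assignment, cluster_a, record$partner_a, threshold)
  pb <- partner_mean(matrix, assignment, cluster_b, record$partner_b, threshold)
  tested <- pa$qualifies && pb$qualifies
  data.frame(cluster_a = cluster_a, cluster_b = cluster_b,
             interaction = record$id,
             effective_a = pa$effective_gene, effective_b = pb$effective_gene,
             mean = if (tested) (pa$mean + pb$mean) / 2 else NA_real_,
             tested = tested,
             autocrine = identical(cluster_a, cluster_b),
             stringsAsFactors = FALSE)
}

# Comparisons of permuted against observed means use a small absolute slack
# so that an arithmetically identical mean recomputed in a different order
# still counts as "as high".
.mean_tol <- 1e-9

#' Permutation test for cluster-pair-specific ligand-receptor interactions
#'
#' For every ordered cluster pair and every interaction, computes the
#' observed statistic ([observed_interaction_mean()]) and a permutation
#' p-value: cluster labels of all cells are globally shuffled
#' `n_permutations` times, the statistic recomputed under each shuffle with
#' the expression-fraction filter and complex effective genes held fixed at
#' their observed-label decisions, and p is the proportion of null means as
#' high or higher than the observed mean. Each interaction record is thereby
#' evaluated in both orientations (its partner_a in cluster i with partner_b
#' in cluster j, and the reverse), one row per orientation; autocrine
#' (same-cluster) rows are computed but flagged.
#'
#' With `add_one = FALSE` (default) p is the plain proportion k/N and may be
#' exactly 0; `add_one = TRUE` uses the (k+1)/(N+1) estimator. A
#' Benjamini-Hochberg q-value over tested rows is reported as an extra
#' column but never used for filtering.
#'
#' @param matrix genes x cells matrix on the scale the statistic should use
#'   (conventionally log(TPM+1)).
#' @param assignment cluster labels aligned with columns (>= 2 clusters).
#' @param records an `lr_db` or list of [lr_record()]s.
#' @param n_permutations label shuffles (default 1000).
#' @param threshold expression-fraction filter (default 0.10, strict).
#' @param seed RNG seed; results are deterministic given it.
#' @param add_one use the add-one p-value estimator.
#' @param include_autocrine include same-cluster pairs (flagged) in the
#'   output (default TRUE).
#' @return long-format data.frame over ordered cluster pairs x interactions:
#'   `cluster_a`, `cluster_b`, `interaction`, `effective_a`, `effective_b`,
#'   `mean`, `p`, `q`, `tested`, `autocrine`, `n_permutations`. `p` and `q`
#'   are NA for untested rows.
#' @export
permutation_pvalues <- function(matrix, assignment, records,
                                n_permutations = 1000, threshold = 0.10,
                                seed = 0, add_one = FALSE,
                                include_autocrine = TRUE) {
  check_matrix(matrix, require_nonneg = FALSE)
  labels <- as_cluster_labels(assignment)
  if (length(labels) != ncol(matrix)) {
    stop("assignment does not match matrix columns")
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)")
  prof <- cluster_profile(matrix, labels)
  clusters <- prof$clusters
  if (length(clusters) < 2) stop("need at least 2 clusters")

  pairs <- expand.grid(a = clusters, b = clusters,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (!include_autocrine) pairs <- pairs[pairs$a != pairs$b, ]

  rows <- vector("list", nrow(pairs) * length(records))
  r <- 0L
  for (rec in records) {
    # per-cluster qualification and effective gene, decided once on the
    # observed labels and reused for every pair and permutation
    score_partner <- function(partner) {
      sub_mean <- prof$mean[partner, , drop = FALSE]
      sub_frac <- prof$frac[partner, , drop = FALSE]
      eff_idx <- apply(sub_mean, 2, which.min)
      list(eff = partner[eff_idx],
           mean = sub_mean[cbind(eff_idx, seq_along(clusters))],
           ok = apply(sub_frac > threshold, 2, all))
    }
    pa <- score_partner(rec$partner_a)
    pb <- score_partner(rec$partner_b)
    ia <- match(pairs$a, clusters)
    ib <- match(pairs$b, clusters)
    for (j in seq_len(nrow(pairs))) {
      r <- r + 1L
      tested <- pa$ok[ia[j]] && pb$ok[ib[j]]
      rows[[r]] <- data.frame(
        cluster_a = pairs$a[j], cluster_b = pairs$b[j],
        interaction = rec$id,
        effective_a = pa$eff[ia[j]], effective_b = pb$eff[ib[j]],
        mean = if (tested) (pa$mean[ia[j]] + pb$mean[ib[j]]) / 2 else NA_real_,
        tested = tested,
        autocrine = pairs$a[j] == pairs$b[j],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  tested_idx <- which(out$tested)
  counts <- integer(length(tested_idx))
  if (length(tested_idx) > 0) {
    genes_needed <- unique(c(out$effective_a[tested_idx],
                             out$effective_b[tested_idx]))
    en <- matrix[genes_needed, , drop = FALSE]
    ga <- match(out$effective_a[tested_idx], genes_needed)
    gb <- match(out$effective_b[tested_idx], genes_needed)
    ca <- match(out$cluster_a[tested_idx], clusters)
    cb <- match(out$cluster_b[tested_idx], clusters)
    obs <- out$mean[tested_idx]
    sizes <- prof$sizes
    n <- length(labels)
    set.seed(seed)
    for (b in seq_len(n_permutations)) {
      perm <- sample(labels)
      ind <- matrix(0, n, length(clusters))
      ind[cbind(seq_len(n), match(perm, clusters))] <- 1
      mp <- sweep(en %*% ind, 2, sizes, "/")
      null_mean <- (mp[cbind(ga, ca)] + mp[cbind(gb, cb)]) / 2
      counts <- counts + (null_mean >= obs - .mean_tol)
    }
  }
  out$p <- NA_real_
  out$p[tested_idx] <- if (add_one) (counts + 1) / (n_permutations + 1)
                       else counts / n_permutations
  out$q <- NA_real_
  out$q[tested_idx] <- p.adjust(out$p[tested_idx], method = "BH")
  out$n_permutations <- ifelse(out$tested, n_permutations, NA_integer_)
  rownames(out) <- NULL
  out
}

# All distinct orderings of a label multiset (recursive; small inputs only).
multiset_permutations <- function(labels) {
  uniq <- unique(labels)
  if (length(labels) <= 1) return(list(labels))
  out <- list()
  for (u in uniq) {
    rest <- labels[-match(u, labels)]
    for (p in multiset_permutations(rest)) out <- c(out, list(c(u, p)))
  }
  out
}

#' Exact permutation p-value by exhaustive enumeration
#'
#' Independent oracle for [permutation_pvalues()]: enumerates every distinct
#' assignment of the observed label multiset to the cells (preserving
#' cluster sizes), recomputes the interaction statistic under each, and
#' returns the exact proportion of assignments whose mean is as high or
#' higher than the observed one. Only feasible for small instances; inputs
#' above 12 cells are rejected.
#'
#' @inheritParams observed_interaction_mean
#' @return list with `p` (exact), `observed` mean, and `n_assignments`.
#' @export
exhaustive_pvalues <- function(matrix, assignment, record, cluster_a,
                               cluster_b, threshold = 0.10) {
  check_matrix(matrix, require_nonneg = FALSE)
  labels <- as_cluster_labels(assignment)
  if (length(labels) > 12) stop("exhaustive oracle limited to <= 12 cells")
  obs_row <- observed_interaction_mean(matrix, assignment, cluster_a,
                                       cluster_b, record, threshold)
  if (!obs_row$tested) stop("interaction is not tested under observed labels")
  eff_a <- obs_row$effective_a
  eff_b <- obs_row$effective_b
  perms <- multiset_permutations(unname(labels))
  null_means <- vapply(perms, function(p) {
    (mean(matrix[eff_a, p == cluster_a]) +
       mean(matrix[eff_b, p == cluster_b])) / 2
  }, numeric(1))
  list(p = mean(null_means >= obs_row$mean - .mean_tol),
       observed = obs_row$mean,
       n_assignments = length(perms))
}

#' Filter and order interaction results
#'
#' @param results output of [permutation_pvalues()].
#' @param alpha significance level; rows with `p <= alpha` are significant.
#' @return list with `significant` (tested rows at `p <= alpha`, sorted by
#'   cluster pair then p) and `full` (all rows, same ordering).
#' @export
summarize_significant <- function(results, alpha = 0.05) {
  ord <- order(results$cluster_a, results$cluster_b, results$p)
  full <- results[ord, ]
  rownames(full) <- NULL
  sig <- full[full$tested & !is.na(full$p) & full$p <= alpha, ]
  rownames(sig) <- NULL
  list(significant = sig, full = full)
}
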