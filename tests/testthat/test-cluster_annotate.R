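test_that("highly variable gene selection ranks by binned dispersion", {
  set.seed(1)
  base <- matrix(rnorm(50 * 30, mean = 5, sd = 1), 50, 30)
  m <- toy_matrix(base)
  m[7, ] <- 5 + rnorm(30, sd = 10)  # same mean, 100x the variance
  expect_equal(select_hvg(m, 1), "g7")
  expect_warning(all_genes <- select_hvg(m, 100), "exceeds")
  expect_setequal(all_genes, rownames(m))

  flat <- toy_matrix(matrix(3, 10, 5))
  expect_error(select_hvg(flat, 2), "no variable genes")
})

test_that("PCA embedding is deterministic with fixed sign and ordered variance", {
  sim <- small_sim(12)
  lg <- log_transform(strip_spikeins_rescale(sim$matrix))
  emb <- pca_embed(lg, n_pcs = 10)
  expect_identical(emb, pca_embed(lg, n_pcs = 10))
  sdev <- attr(emb, "sdev")
  expect_true(all(diff(sdev) <= 1e-12))
  # largest-magnitude loading of each component is positive
  rot <- attr(emb, "rotation")
  tops <- apply(rot, 2, function(w) w[which.max(abs(w))])
  expect_true(all(tops > 0))

  # duplicated gene rows load identically on PC1
  dup <- lg[c(1, 1, 2:60), ]
  rownames(dup)[1:2] <- c("dupA", "dupB")
  rot2 <- attr(pca_embed(dup, n_pcs = 5), "rotation")
  expect_equal(rot2["dupA", 1], rot2["dupB", 1], tolerance = 1e-9)

  expect_warning(small <- pca_embed(lg[1:5, ], n_pcs = 20), "rank")
  expect_lte(ncol(small), 5)
})

test_that("PC1 separates two strongly distinct clusters with no overlap", {
  cfg <- sim_config(seed = 13, n_clusters = 2, cells_per_cluster = 30,
                    n_genes = 400, n_marker_genes_per_cluster = 40,
                    n_mito_genes = 4, n_ercc = 8, marker_fold = 8,
                    dropout_rate = 0)
  sim <- simulate_matrix(cfg)
  lg <- log_transform(strip_spikeins_rescale(sim$matrix))
  emb <- pca_embed(lg, n_pcs = 10)
  cl <- sim$truth$cell_cluster
  r0 <- range(emb[cl == 0, 1]); r1 <- range(emb[cl == 1, 1])
  expect_true(r0[2] < r1[1] || r1[2] < r0[1])
})

test_that("SNN community detection recovers separated blobs deterministically", {
  set.seed(2)
  blob <- function(center, n) sweep(matrix(rnorm(n * 5), n, 5), 2, center, "+")
  emb <- rbind(blob(rep(0, 5), 30), blob(rep(100, 5), 30))
  rownames(emb) <- paste0("c", 1:60)
  asg <- cluster_snn(emb, k_neighbors = 10, resolution = 0.8, seed = 0)
  expect_equal(length(unique(asg$cluster)), 2)
  truth <- rep(0:1, each = 30)
  expect_equal(adjusted_rand_index(asg$cluster, truth), 1)
  expect_identical(asg$cluster,
                   cluster_snn(emb, 10, 0.8, seed = 0)$cluster)
  expect_equal(sort(unique(unname(asg$cluster))), 0:1)

  # vanishing resolution on a connected graph: one community
  one <- cluster_snn(emb[1:30, ], 10, resolution = 1e-4, seed = 0)
  expect_equal(length(unique(one$cluster)), 1)

  expect_error(cluster_snn(emb[1:5, ], k_neighbors = 10), "k_neighbors")
})

test_that("Wilcoxon marker test matches the textbook statistic and wilcox.test", {
  m <- toy_matrix(rbind(c(1, 2, 3, 4, 5, 6)))
  labels <- c(0, 0, 0, 1, 1, 1)
  res <- rank_markers_wilcoxon(m, labels, 0)
  expect_equal(res$statistic, 0)  # in-group wholly below out-group

  # identical values in both groups: p = 1
  flat <- toy_matrix(rbind(rep(2, 8)))
  expect_equal(rank_markers_wilcoxon(flat, rep(0:1, 4), 0)$p, 1)

  # oracle: stats::wilcox.test normal approximation with tie correction
  set.seed(3)
  rand <- toy_matrix(matrix(rpois(20 * 12, 3), 20, 12))
  labels <- rep(c(0, 1), each = 6)
  mine <- rank_markers_wilcoxon(rand, labels, 0)
  ref <- vapply(rownames(rand), function(g) {
    suppressWarnings(stats::wilcox.test(rand[g, labels == 0],
                                        rand[g, labels == 1],
                                        exact = FALSE, correct = FALSE)$p.value)
  }, numeric(1))
  expect_equal(mine$p[match(names(ref), mine$gene)], unname(ref),
               tolerance = 1e-9)
  expect_true(all(mine$p_adj >= mine$p))
  expect_error(rank_markers_wilcoxon(rand, labels, 7), "cluster")
})

test_that("planted markers rank on top with adjusted significance", {
  sim <- small_sim(14, dropout_rate = 0, marker_fold = 8)
  lg <- log_transform(strip_spikeins_rescale(sim$matrix))
  res <- rank_markers_wilcoxon(lg, sim$truth$cell_cluster, 1)
  top <- res$gene[seq_len(30)]
  expect_gte(mean(sim$truth$marker_genes[["1"]] %in% top), 0.9)
  planted <- res[res$gene %in% sim$truth$marker_genes[["1"]], ]
  expect_true(all(planted$p_adj < 0.05))
  expect_true(all(planted$lfc > 0))
})

test_that("Wilcoxon p-values are calibrated under the global null", {
  set.seed(4)
  null_mat <- toy_matrix(matrix(rlnorm(2500 * 60, 2, 0.7), 2500, 60))
  labels <- rep(c(0, 1), each = 30)
  res <- rank_markers_wilcoxon(null_mat, labels, 0)
  rej <- mean(res$p <= 0.05)
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.07)
})

test_that("module scores are centered under the null and shifted for markers", {
  set.seed(5)
  flat <- toy_matrix(matrix(rlnorm(400 * 50, 1, 0.5), 400, 50))
  sc <- module_score(flat, rownames(flat)[1:25], seed = 1)
  expect_lt(abs(mean(sc)), 0.08)
  expect_identical(sc, module_score(flat, rownames(flat)[1:25], seed = 1))

  sim <- small_sim(15)
  lg <- log_transform(strip_spikeins_rescale(sim$matrix))
  cl <- sim$truth$cell_cluster
  sc2 <- module_score(lg, sim$truth$marker_genes[["0"]], seed = 1)
  expect_gt(mean(sc2[cl == 0]), max(tapply(sc2[cl != 0], cl[cl != 0], mean)))

  expect_error(module_score(lg, c("nope1", "nope2")), "intersect")
})

test_that("covariate regression leaves orthogonal residuals with means kept", {
  sim <- small_sim(16)
  lg <- log_transform(strip_spikeins_rescale(sim$matrix))[1:100, ]
  cov <- rnorm(ncol(lg))
  res <- regress_out(lg, cov)
  cors <- apply(res, 1, function(x) {
    if (sd(x) < 1e-12) 0 else cor(x, cov)
  })
  expect_true(all(abs(cors) < 1e-9))
  expect_equal(rowMeans(res), rowMeans(lg), tolerance = 1e-9)

  # exact linear gene collapses to its mean
  m2 <- toy_matrix(rbind(2 * cov, rnorm(length(cov))))
  res2 <- regress_out(m2, cov)
  expect_equal(unname(res2[1, ]), rep(mean(m2[1, ]), ncol(m2)),
               tolerance = 1e-9)

  expect_warning(unchanged <- regress_out(lg, rep(1, ncol(lg))), "constant")
  expect_identical(unchanged, lg)
})

test_that("cell-cycle pair scores count strict exceedances", {
  m <- toy_matrix(cbind(c(5, 1, 4, 2, 3, 3), c(0, 0, 0, 0, 0, 0)),
                  genes = c("a1", "a2", "b1", "b2", "c1", "c2"))
  pairs <- data.frame(first = c("a1", "b1", "c1"),
                      second = c("a2", "b2", "c2"))
  sc <- cell_cycle_score(m, pairs)
  expect_equal(unname(sc), c(2 / 3, 0))  # ties are not greater; zeros score 0

  all_up <- toy_matrix(cbind(c(5, 1, 4, 2, 9, 3)),
                       genes = c("a1", "a2", "b1", "b2", "c1", "c2"))
  expect_equal(unname(cell_cycle_score(all_up, pairs)), 1)

  expect_error(cell_cycle_score(m, data.frame(first = "x", second = "y")),
               "usable")
  expect_error(cell_cycle_score(m, data.frame(first = "a1", second = "a1")),
               "identical")
})

test_that("phase assignment needs a dominant qualifying score", {
  sc <- rbind(c(G1 = 0.1, S = 0.1, G2M = 0.9),
              c(G1 = 0.5, S = 0.5, G2M = 0.5),
              c(G1 = 0.2, S = 0.3, G2M = 0.4),
              c(G1 = 0.8, S = 0.8, G2M = 0.1))
  expect_equal(unname(assign_phase(sc)),
               c("G2M", "unassigned", "unassigned", "unassigned"))
  expect_error(assign_phase(rbind(c(G1 = 1.2, S = 0))), "0, 1")
})

test_that("marker-pair CSV round-trips by phase", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("phase,first,second", "G2M,a,b", "G2M,c,d", "S,e,f"), f)
  ps <- read_marker_pairs(f)
  expect_named(ps, c("G2M", "S"))
  expect_equal(nrow(ps$G2M), 2)
})
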