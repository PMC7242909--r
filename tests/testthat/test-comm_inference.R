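write_db <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("interaction CSV parsing handles complexes and rejects bad rows", {
  db <- load_interaction_db(write_db(c("id,partner_a,partner_b",
                                       "I1,L1,R1",
                                       "I2,L1,R1+R2+R3")))
  expect_length(db, 2)
  expect_equal(db[[1]]$partner_a, "L1")
  expect_equal(db[[2]]$partner_b, c("R1", "R2", "R3"))

  expect_error(load_interaction_db(write_db(c("id,partner_a,partner_b",
                                              "I1,L1,R1", "I1,L2,R2"))),
               "duplicate")
  expect_error(load_interaction_db(write_db(c("id,partner_a,partner_b",
                                              "I1,L1,R1", "I2,,R2"))),
               "line 3")
  expect_error(load_interaction_db(write_db(c("id,partner_a,partner_b",
                                              "I1,L1,R1+R1"))),
               "line 2")
  expect_error(load_interaction_db(write_db(c("a,b", "1,2"))), "columns")
})

test_that("expressed fraction counts strictly positive cells", {
  m <- toy_matrix(rbind(c(rep(1, 3), rep(0, 7)), rep(0, 10)),
                  genes = c("A", "B"))
  labels <- rep(0, 10)
  expect_equal(expressed_fraction(m, labels, 0, "A"), 0.3)
  expect_equal(expressed_fraction(m, labels, 0, "B"), 0)
  expect_error(expressed_fraction(m, labels, 0, "zz"), "unknown gene")

  # exactly 10% fails the strict filter
  m2 <- toy_matrix(rbind(c(5, rep(0, 9))), genes = "A")
  expect_equal(expressed_fraction(m2, labels, 0, "A"), 0.10)
  expect_false(partner_mean(m2, labels, 0, "A")$qualifies)
})

test_that("complex partners use the minimum-average subunit after full detection", {
  labels <- rep(0, 4)
  m <- toy_matrix(rbind(rep(5, 4), rep(2, 4), rep(9, 4), rep(0, 4)),
                  genes = c("S1", "S2", "S3", "S4"))
  pm <- partner_mean(m, labels, 0, "S1+S2+S3")
  expect_true(pm$qualifies)
  expect_equal(pm$mean, 2.0)
  expect_equal(pm$effective_gene, "S2")

  silent <- partner_mean(m, labels, 0, "S1+S4")
  expect_false(silent$qualifies)

  simple <- partner_mean(toy_matrix(rbind(A = rep(4, 5)), genes = "A"),
                         rep(0, 5), 0, "A")
  expect_true(simple$qualifies)
  expect_equal(simple$mean, 4)
})

test_that("observed statistic averages the two cluster means when tested", {
  m <- toy_matrix(rbind(c(3, 3, 5, 5), c(3, 3, 5, 5)), genes = c("L", "R"))
  labels <- c(0, 0, 1, 1)
  rec <- lr_record("I", "L", "R")
  row <- observed_interaction_mean(m, labels, 0, 1, rec)
  expect_true(row$tested)
  expect_equal(row$mean, 4)  # (3 + 5) / 2

  # swapping partners and clusters leaves the mean unchanged
  swapped <- observed_interaction_mean(m, labels, 1, 0, lr_record("I", "R", "L"))
  expect_equal(swapped$mean, row$mean)

  # autocrine rows computed the same way and flagged
  auto <- observed_interaction_mean(m, labels, 1, 1, rec)
  expect_true(auto$autocrine)
  expect_equal(auto$mean, 5)

  # partner failing the fraction filter: not tested, no mean
  m2 <- m; m2["R", ] <- 0
  row2 <- observed_interaction_mean(m2, labels, 0, 1, rec)
  expect_false(row2$tested)
  expect_true(is.na(row2$mean))
})

test_that("permutation p-values match the exhaustive oracle on the 6-cell toy", {
  toy <- toy6()
  ex <- exhaustive_pvalues(toy$matrix, toy$labels, toy$record, 0, 1)
  expect_equal(ex$p, 1 / 20)
  expect_equal(ex$n_assignments, 20)

  res <- permutation_pvalues(toy$matrix, toy$labels, list(toy$record),
                             n_permutations = 10000, seed = 2)
  sampled <- res$p[res$cluster_a == 0 & res$cluster_b == 1]
  expect_lt(abs(sampled - ex$p), binom99_halfwidth(ex$p, 10000))

  # symmetric data: p = 1 exactly
  sym <- toy_matrix(rbind(rep(4, 6), rep(4, 6)), genes = c("L1", "R1"))
  exs <- exhaustive_pvalues(sym, toy$labels, toy$record, 0, 1)
  expect_equal(exs$p, 1)
  ress <- permutation_pvalues(sym, toy$labels, list(toy$record),
                              n_permutations = 50, seed = 1)
  expect_equal(ress$p[ress$tested], rep(1, sum(ress$tested)))

  big <- toy_matrix(matrix(1, 2, 13), genes = c("L1", "R1"))
  expect_error(exhaustive_pvalues(big, rep(0:1, length.out = 13),
                                  toy$record, 0, 1), "12 cells")
})

test_that("sampled p-values agree with the oracle across random small instances", {
  set.seed(6)
  for (i in 1:4) {
    n <- sample(6:9, 1)
    k <- sample(2:3, 1)
    labels <- stats::setNames(sort(rep_len(seq_len(k) - 1, n)), paste0("c", 1:n))
    m <- toy_matrix(matrix(rlnorm(2 * n, 1, 1), 2, n), genes = c("L", "R"))
    rec <- lr_record("I", "L", "R")
    ex <- exhaustive_pvalues(m, labels, rec, 0, 1)
    res <- permutation_pvalues(m, labels, list(rec),
                               n_permutations = 4000, seed = i)
    sampled <- res$p[res$cluster_a == 0 & res$cluster_b == 1]
    expect_lt(abs(sampled - ex$p), binom99_halfwidth(ex$p, 4000))
  }
})

test_that("permutation results are deterministic and support add-one estimation", {
  toy <- toy6()
  r1 <- permutation_pvalues(toy$matrix, toy$labels, list(toy$record),
                            n_permutations = 200, seed = 7)
  r2 <- permutation_pvalues(toy$matrix, toy$labels, list(toy$record),
                            n_permutations = 200, seed = 7)
  expect_identical(r1, r2)
  r3 <- permutation_pvalues(toy$matrix, toy$labels, list(toy$record),
                            n_permutations = 200, seed = 7, add_one = TRUE)
  k <- r1$p[r1$tested] * 200
  expect_equal(r3$p[r3$tested], (k + 1) / 201)
})

test_that("planted-pair p-values do not increase with fold", {
  mean_planted_p <- function(fold) {
    ps <- vapply(1:3, function(seed) {
      cfg <- sim_config(seed = seed, n_clusters = 3, cells_per_cluster = 20,
                        n_genes = 300, n_marker_genes_per_cluster = 30,
                        n_mito_genes = 5, n_ercc = 10,
                        lr_signals = list(list(ligand = "Gene0200",
                                               receptor = "Gene0201",
                                               source = 0, target = 1,
                                               fold = fold)))
      sim <- simulate_matrix(cfg)
      lg <- log_transform(strip_spikeins_rescale(sim$matrix))
      res <- permutation_pvalues(lg, sim$truth$cell_cluster,
                                 list(lr_record("P", "Gene0200", "Gene0201")),
                                 n_permutations = 400, seed = seed)
      res$p[res$cluster_a == 0 & res$cluster_b == 1]
    }, numeric(1))
    mean(ps)
  }
  p_low <- mean_planted_p(1.5)
  p_high <- mean_planted_p(8)
  expect_lte(p_high, p_low)
})

test_that("significance summaries filter and order without dropping rows", {
  toy <- toy6()
  res <- permutation_pvalues(toy$matrix, toy$labels, list(toy$record),
                             n_permutations = 100, seed = 3)
  s_all <- summarize_significant(res, alpha = 1)
  expect_equal(nrow(s_all$significant), sum(res$tested))
  expect_equal(nrow(s_all$full), nrow(res))
  s_zero <- summarize_significant(res, alpha = 0)
  expect_true(all(s_zero$significant$p == 0))
  ord <- s_all$full
  expect_true(!is.unsorted(ord$cluster_a))
})

test_that("degenerate identical expression gives p = 1 everywhere", {
  m <- toy_matrix(matrix(2, 2, 8), genes = c("L", "R"))
  labels <- rep(c(0, 1), each = 4)
  res <- permutation_pvalues(m, labels, list(lr_record("I", "L", "R")),
                             n_permutations = 100, seed = 1)
  expect_true(all(res$p[res$tested] == 1))
})
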