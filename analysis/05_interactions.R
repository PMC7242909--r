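#!/usr/bin/env Rscript
# Stage 5: permutation-based ligand-receptor communication inference.
#
# Runs the cluster-label permutation test (1000 global shuffles, 10%
# expression filter, minimum-subunit complex rule) over the stage-1
# interaction database on the QC'd matrix, using the communities found in
# stage 3, and checks the planted signals against the recovered table.

suppressPackageStartupMessages(library(crosstalker))

data_dir <- "results/data"
lg <- read_matrix_mtx(file.path(data_dir, "logtpm"))
clusters <- read.csv(file.path(data_dir, "clusters.csv"))
asg <- setNames(clusters$cluster, clusters$cell)[colnames(lg)]
db <- load_interaction_db(file.path(data_dir, "interaction_db.csv"))
planted <- read.csv(file.path(data_dir, "truth_planted.csv"))

res <- permutation_pvalues(lg, asg, db, n_permutations = 1000,
                           threshold = 0.10, seed = 0)
summ <- summarize_significant(res, alpha = 0.05)
write.table(summ$full, file.path(data_dir, "interactions_full.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(summ$significant, file.path(data_dir, "interactions_sig.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# communities are relabeled arbitrarily; map each planted (source, target)
# through the majority community of its true cluster's cells
truth <- read.csv(file.path(data_dir, "truth_cells.csv"))
truth_cl <- truth$cluster[match(colnames(lg), truth$cell)]
map <- vapply(sort(unique(truth_cl)), function(k) {
  as.integer(names(which.max(table(asg[truth_cl == k]))))
}, integer(1))
hits <- mapply(function(id, src, tgt) {
  row <- subset(summ$full, interaction == paste0("P", id) &
                  cluster_a == map[src + 1] & cluster_b == map[tgt + 1])
  nrow(row) == 1 && isTRUE(row$p < 0.05)
}, seq_len(nrow(planted)), planted$source, planted$target)
message(sprintf("planted signals recovered at p < 0.05: %d/%d",
                sum(hits), nrow(planted)))
tested <- subset(summ$full, tested)
message(sprintf("tested rows: %d; significant: %d (%.1f%%)", nrow(tested),
                nrow(summ$significant),
                100 * nrow(summ$significant) / nrow(tested)))
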