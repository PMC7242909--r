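#!/usr/bin/env Rscript
# Stage 1: build the synthetic experiment every later stage consumes.
#
# Generates a 4-cluster, 200-cell Smart-seq2-style TPM matrix (markers at
# fold 8, 30% dropout, mitochondrial and ERCC spike-in rows) with three
# ligand-receptor signals planted on consecutive cluster pairs (the second
# through a 2-subunit receptor complex) and ten decoy interactions, then
# degrades 10 cells below the detected-gene threshold and pushes 5 cells
# above the mitochondrial limit so stage 2 has something to remove.

suppressPackageStartupMessages(library(crosstalker))

seed <- 1
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

bench <- simulate_communication_benchmark(seed = seed, n_signals = 3,
                                          fold = 8, n_decoys = 10)

# degrade a known set of cells so the QC stage is exercised end to end;
# thresholds scaled to this 2030-gene transcriptome
thr <- qc_thresholds(min_detected_genes = 1000, max_mito_fraction = 0.20)
set.seed(seed)
bad <- inject_qc_failures(bench$matrix, bench$truth, n_low_gene = 10,
                          n_high_mito = 5, thresholds = thr)

write_matrix_mtx(bad$matrix, file.path(out, "tpm"))
write.csv(data.frame(cell = names(bad$truth$cell_cluster),
                     cluster = bad$truth$cell_cluster,
                     low_quality = names(bad$truth$cell_cluster) %in%
                       bad$truth$low_quality_cells),
          file.path(out, "truth_cells.csv"), row.names = FALSE)
db_df <- do.call(rbind, lapply(bad$truth$planted, function(r) {
  data.frame(id = r$id, ligand = paste(r$ligand, collapse = "+"),
             receptor = paste(r$receptor, collapse = "+"),
             source = r$source, target = r$target, fold = r$fold)
}))
write.csv(db_df, file.path(out, "truth_planted.csv"), row.names = FALSE)
write.csv(data.frame(
  id = vapply(bench$db, `[[`, "", "id"),
  partner_a = vapply(bench$db, function(r) paste(r$partner_a, collapse = "+"), ""),
  partner_b = vapply(bench$db, function(r) paste(r$partner_b, collapse = "+"), "")),
  file.path(out, "interaction_db.csv"), row.names = FALSE)

message(sprintf("wrote %d genes x %d cells to %s (%d QC failures injected)",
                nrow(bad$matrix), ncol(bad$matrix), out,
                length(bad$truth$low_quality_cells)))
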