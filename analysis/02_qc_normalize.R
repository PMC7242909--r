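#!/usr/bin/env Rscript
# Stage 2: quality control and spike-in-aware renormalization.
#
# Reads the stage-1 TPM matrix, drops cells below the detected-gene
# threshold or above the mitochondrial limit (strict boundaries), removes
# genes expressed in fewer than 3 cells, strips the ERCC rows, rescales each
# cell back to one million, and stores the log(TPM+1) matrix.

suppressPackageStartupMessages(library(crosstalker))

data_dir <- "results/data"
tpm <- read_matrix_mtx(file.path(data_dir, "tpm"))
truth <- read.csv(file.path(data_dir, "truth_cells.csv"))

qc <- compute_qc_metrics(tpm)
write.csv(qc, file.path(data_dir, "qc_metrics.csv"), row.names = FALSE)

thr <- qc_thresholds(min_detected_genes = 1000, max_mito_fraction = 0.20)
kept <- filter_cells(tpm, qc, thr)
removed <- setdiff(colnames(tpm), colnames(kept))
injected <- truth$cell[truth$low_quality]
message(sprintf("removed %d cells; %d/%d match the injected failures",
                length(removed), length(intersect(removed, injected)),
                length(injected)))

kept <- filter_genes(kept, min_cells_per_gene = 3)
lg <- log_transform(strip_spikeins_rescale(kept))
stopifnot(all(!grepl("^ERCC-", rownames(lg))))
write_matrix_mtx(lg, file.path(data_dir, "logtpm"))
message(sprintf("normalized matrix: %d genes x %d cells", nrow(lg), ncol(lg)))
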