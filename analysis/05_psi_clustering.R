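#!/usr/bin/env Rscript

# Stage 5 — PSI quantitation and clustering.
#
# Regenerates isoform measurements for the planted 10-event x 6-sample
# truth (two opposed inclusion patterns), computes PSI per cell, clusters
# rows and columns hierarchically (Euclidean, average linkage), and checks
# that the two planted splicing patterns come out contiguous in leaf order.

suppressPackageStartupMessages(library(meiosplice))
SEED <- 101

gm <- gen_isoform_measurements(synth_config(seed = SEED))
m <- build_psi_matrix(gm$measurements)
cl <- cluster_psi_matrix(m)

write_psi_matrix(cl, "results/psi_matrix.tsv",
                 "results/psi_cluster_orders.tsv")

cat("PSI matrix (", nrow(m), "events x", ncol(m), "samples ), clustered.\n")
cat("Row leaf order: ", paste(cl$row_order, collapse = " "), "\n")
groups <- ifelse(gm$truth[cl$row_order, 1] > 50, "high-first", "low-first")
cat("Planted pattern blocks in leaf order:",
    paste(rle(groups)$values, collapse = " | "),
    "->", if (length(rle(groups)$values) == 2) "contiguous" else "mixed",
    "\n")
err <- abs(m[rownames(gm$truth), colnames(gm$truth)] - gm$truth)
cat(sprintf("Mean |PSI - truth| = %.2f (noise sd %.0f%%)\n", mean(err), 5))
cat("Written results/psi_matrix.tsv and results/psi_cluster_orders.tsv\n")
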