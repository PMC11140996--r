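#!/usr/bin/env Rscript
# Stage 3 — graph-based clustering of QC-passing cells (delegating stage:
# HVG / PCA / SNN graph / Louvain via scran + igraph).

suppressPackageStartupMessages(library(ctxneu))

sce <- read_dataset("results/data")
qc <- read.delim("results/02_qc_report.tsv")
kept <- sce[, qc$pass_filters]

cl <- cluster_cells(kept, n_hvg = 1000, n_pcs = 15, k_neighbors = 20,
                    resolution = 0.8, seed = 201L)
print(cl)
write.table(data.frame(cell_id = names(cl$labels),
                       cluster = as.character(cl$labels)),
            "results/03_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- as.data.frame(SummarizedExperiment::colData(kept))$true_cell_type
tab <- table(cluster = cl$labels, type = truth)
print(tab)
message("wrote results/03_clusters.tsv")
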