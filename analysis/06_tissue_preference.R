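#!/usr/bin/env Rscript
# Stage 6 — tissue preference of the clusters by Ro/e (ratio of observed
# to expected cell numbers under the independence model).

suppressPackageStartupMessages(library(ctxneu))

sce <- read_dataset("results/data")
qc <- read.delim("results/02_qc_report.tsv")
clusters <- read.delim("results/03_clusters.tsv")
kept <- sce[, qc$pass_filters]
md <- as.data.frame(SummarizedExperiment::colData(kept))

r <- roe(clusters$cluster[match(md$cell_id, clusters$cell_id)], md$tissue)
print(r)
write.table(roe_table(r), "results/06_roe.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("values above 1 mark tissue enrichment of a cluster")
message("wrote results/06_roe.tsv")
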