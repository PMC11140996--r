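#!/usr/bin/env Rscript
# Stage 5 — context-dependent neutrophil activation scores.
#
# Three bimod DEG contrasts over blood / peritumor / tumor neutrophils
# (fold change > 1.2, p < 0.001), directional intersection, fold-change
# ranking, truncation to the top 21 genes per score, and per-cell
# average-expression scoring.

suppressPackageStartupMessages(library(ctxneu))

sce <- read_dataset("results/data")
qc <- read.delim("results/02_qc_report.tsv")
kept <- sce[, qc$pass_filters]
md <- as.data.frame(SummarizedExperiment::colData(kept))
neu <- kept[, md$true_cell_type == "neutrophil"]

cs <- build_context_scores(neu, top_n = 21)
print(cs)
for (nm in names(cs$provenance)) {
  write.table(cs$provenance[[nm]],
              paste0("results/05_degs_", nm, ".tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(data.frame(score = rep(names(cs$sets), lengths(cs$sets)),
                       gene_id = unlist(cs$sets, use.names = FALSE)),
            "results/05_context_sets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cs$scores, "results/05_context_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# planted-truth recovery against the generator's programs
design <- read_design("results/design.yaml")
planted <- setNames(lapply(design$programs, `[[`, "genes"),
                    vapply(design$programs, `[[`, "", "name"))
pairing <- c(nontumor_activating = "nontumor_shared",
             tissue_residing = "tissue_shared",
             tumor_modifying = "tumor_specific")
for (nm in names(pairing)) {
  got <- cs$sets[[nm]]
  message(sprintf("%s: %d/%d genes from planted program '%s'", nm,
                  sum(got %in% planted[[pairing[[nm]]]]), length(got),
                  pairing[[nm]]))
}
agg <- aggregate(cs$scores[names(cs$sets)],
                 by = list(tissue = cs$scores$tissue), FUN = mean)
print(agg, digits = 3)
message("wrote results/05_context_*.tsv")
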