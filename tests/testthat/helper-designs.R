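# shared fixture builders: every dataset is generated in code at test time

# two well-separated cell types in one sample
two_type_design <- function(seed, cells_per_sample = 400, doublet_rate = 0,
                            log2_effect = 3) {
  synthetic_design(
    n_genes = 1000, n_patients = 1, tissues = "tumor",
    cells_per_sample = cells_per_sample, n_chromosomes = 3,
    cell_type_props = list(tumor = c(neutrophil = 0.5, epithelial = 0.5)),
    programs = list(
      gene_program("neu_identity", paste0("G", 1:40), "tumor", log2_effect,
                   cell_types = "neutrophil"),
      gene_program("epi_identity", paste0("G", 41:80), "tumor", log2_effect,
                   cell_types = "epithelial")),
    doublet_rate = doublet_rate, mito_high_fraction = 0, seed = seed)
}

# flat design: no programs, no CNV, no doublets, no damaged cells
null_design <- function(seed, n_genes = 500, cells_per_sample = 150,
                        tissues = c("blood", "peritumor", "tumor")) {
  synthetic_design(
    n_genes = n_genes, n_patients = 1, tissues = tissues,
    cells_per_sample = cells_per_sample, n_chromosomes = 3,
    cell_type_props = stats::setNames(
      rep(list(c(neutrophil = 1)), length(tissues)), tissues),
    doublet_rate = 0, mito_high_fraction = 0, seed = seed)
}

# tiny SingleCellExperiment from an explicit dense counts matrix
toy_sce <- function(counts, is_mito = rep(FALSE, nrow(counts)),
                    chromosome = NULL, tissue = NULL) {
  n_genes <- nrow(counts)
  gene_id <- if (!is.null(rownames(counts))) rownames(counts)
             else paste0("G", seq_len(n_genes))
  if (is.null(chromosome)) {
    chromosome <- ifelse(is_mito, "chrM", "chr1")
  }
  cell_id <- if (!is.null(colnames(counts))) colnames(counts)
             else paste0("c", seq_len(ncol(counts)))
  cd <- data.frame(cell_id = cell_id, row.names = cell_id)
  if (!is.null(tissue)) cd$tissue <- tissue
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = Matrix::Matrix(counts, sparse = TRUE,
                                          dimnames = list(gene_id, cell_id))),
    colData = S4Vectors::DataFrame(cd),
    rowData = S4Vectors::DataFrame(
      gene_id = gene_id, chromosome = chromosome,
      start_position = stats::ave(seq_len(n_genes), chromosome,
                                  FUN = seq_along) * 1e5,
      is_mitochondrial = is_mito, row.names = gene_id))
}

# brute-force CNV score: double loop over windows and genes on the raw
# relative matrix — the independent oracle for the pipeline score
brute_force_cnv_score <- function(rel, windows) {
  cells <- colnames(rel)
  score <- stats::setNames(numeric(length(cells)), cells)
  for (ci in seq_along(cells)) {
    ss <- 0
    for (w in windows) {
      tot <- 0
      for (g in w$genes) tot <- tot + rel[g, ci]
      ss <- ss + (tot / length(w$genes))^2
    }
    score[ci] <- ss / length(windows)
  }
  score
}

# fixture with exactly known detected-gene counts and mito fractions
qc_boundary_fixture <- function() {
  n_genes <- 1000
  is_mito <- c(rep(TRUE, 100), rep(FALSE, 900))
  cell <- function(n_mito_genes, mito_count_each, n_other, other_counts) {
    v <- numeric(n_genes)
    if (n_mito_genes > 0) v[seq_len(n_mito_genes)] <- mito_count_each
    if (n_other > 0) v[100 + seq_len(n_other)] <- other_counts
    v
  }
  counts <- cbind(
    just_under_genes = cell(9, 1, 240, 1),          # 249 genes, 3.6% mito
    at_gene_boundary = cell(75, 1, 175, 1),         # 250 genes, mito = 0.30
    over_mito = cell(100, 31, 900,
                     rep(c(8, 7), c(600, 300))),    # 1000 genes, mito = 0.31
    empty = cell(0, 0, 0, 0),                       # zero total counts
    clean = cell(10, 1, 500, 2))                    # 510 genes, ~1% mito
  toy_sce(counts, is_mito = is_mito)
}
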