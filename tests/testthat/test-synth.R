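test_that("design validation rejects malformed inputs", {
  expect_error(synthetic_design(nb_dispersion = -1), "nb_dispersion")
  expect_error(synthetic_design(malignant_fraction = 1.5), "must lie")
  expect_error(cnv_segment("chr1", 10, 5, 2), "start < end")
  expect_error(cnv_segment("chr1", 1, 50, 1), "copy_ratio")
  # program referencing a tissue absent from the design
  expect_error(synthetic_design(
    tissues = c("blood", "peritumor", "tumor"),
    programs = list(gene_program("p", "G1", "liver", 1))), "tissue")
  # overlapping program gene sets
  expect_error(synthetic_design(
    programs = list(gene_program("p1", c("G1", "G2"), "tumor", 1),
                    gene_program("p2", c("G2", "G3"), "tumor", 1))),
    "overlap")
  # program on a mitochondrial gene
  expect_error(synthetic_design(
    programs = list(gene_program("p", "MT-1", "tumor", 1))),
    "mitochondrial")
  # segment exceeding its chromosome
  expect_error(synthetic_design(
    cnv_segments = list(cnv_segment("chr1", 1, 10000, 2))), "exceeds")
})

test_that("synthetic genome layout is ordered and flagged", {
  anno <- design_gene_anno(synthetic_design(n_genes = 1000,
                                            n_chromosomes = 4))
  expect_equal(nrow(anno), 1000)
  expect_equal(sum(anno$is_mitochondrial), 25)
  expect_true(all(anno$chromosome[anno$is_mitochondrial] == "chrM"))
  expect_false(anyDuplicated(anno$gene_id) > 0)
  for (chr in unique(anno$chromosome)) {
    pos <- anno$start_position[anno$chromosome == chr]
    expect_true(all(diff(pos) > 0))
  }
})

test_that("generation is bit-identical under a fixed seed", {
  d <- synthetic_design(n_genes = 300, cells_per_sample = 40, seed = 7)
  a <- generate_dataset(d)
  b <- generate_dataset(d)
  expect_identical(SummarizedExperiment::assay(a, "counts"),
                   SummarizedExperiment::assay(b, "counts"))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
})

test_that("a flat design shows no tissue effect beyond sampling noise", {
  sce <- generate_dataset(null_design(seed = 11))
  md <- as.data.frame(SummarizedExperiment::colData(sce))
  cts <- SummarizedExperiment::assay(sce, "counts")
  a <- md$tissue == "blood"
  b <- md$tissue == "tumor"
  # independent per-gene check: two-sided rank test on raw counts
  p <- vapply(seq_len(nrow(cts)), function(g) {
    suppressWarnings(wilcox.test(cts[g, a], cts[g, b],
                                 exact = FALSE)$p.value)
  }, 0)
  expect_gte(mean(p >= 0.001, na.rm = TRUE), 0.99)
})

test_that("a planted copy-ratio-2 segment doubles segment-gene means", {
  d <- synthetic_design(
    n_genes = 1200, n_patients = 1, tissues = "tumor",
    cells_per_sample = 400, n_chromosomes = 3,
    cnv_segments = list(cnv_segment("chr1", 31, 330, copy_ratio = 2.0)),
    cell_type_props = list(tumor = c(epithelial = 1)),
    malignant_fraction = 0.5, doublet_rate = 0, mito_high_fraction = 0,
    seed = 13)
  sce <- generate_dataset(d)
  md <- as.data.frame(SummarizedExperiment::colData(sce))
  cts <- SummarizedExperiment::assay(sce, "counts")
  anno <- as.data.frame(SummarizedExperiment::rowData(sce))
  chr1 <- anno$gene_id[anno$chromosome == "chr1"]
  seg <- chr1[31:330]
  expect_gte(sum(md$true_is_malignant), 200)
  expect_gte(sum(!md$true_is_malignant), 200)
  # oracle: ratio of planted NB means is exactly the copy ratio
  ratio <- mean(Matrix::rowMeans(cts[seg, md$true_is_malignant])) /
    mean(Matrix::rowMeans(cts[seg, !md$true_is_malignant]))
  expect_gte(ratio, 1.8)
  expect_lte(ratio, 2.2)
})

test_that("planted program effect is recovered at the designed magnitude", {
  d <- synthetic_design(
    n_genes = 600, n_patients = 1, tissues = c("blood", "tumor"),
    cells_per_sample = 500, n_chromosomes = 3,
    cell_type_props = list(blood = c(neutrophil = 1),
                           tumor = c(neutrophil = 1)),
    programs = list(gene_program("p", paste0("G", seq(1, 120, 4)),
                                 "tumor", log2_effect = 1.5)),
    doublet_rate = 0, mito_high_fraction = 0, seed = 5)
  sce <- generate_dataset(d)
  md <- as.data.frame(SummarizedExperiment::colData(sce))
  cts <- SummarizedExperiment::assay(sce, "counts")
  genes <- d$programs[[1]]$genes
  lfc <- log2(Matrix::rowMeans(cts[genes, md$tissue == "tumor"]) /
                Matrix::rowMeans(cts[genes, md$tissue == "blood"]))
  expect_lt(abs(mean(lfc) - 1.5), 0.2)
})

test_that("doublets are flagged truthfully and built from larger sums", {
  d <- synthetic_design(n_genes = 300, n_patients = 1,
                        cells_per_sample = 100, doublet_rate = 0.1,
                        mito_high_fraction = 0, seed = 3)
  sce <- generate_dataset(d)
  md <- as.data.frame(SummarizedExperiment::colData(sce))
  expect_equal(sum(md$true_is_doublet), 3 * 10)  # 3 tissues x 10%
  # pre-downscaling sums exceed either parent by construction
  x <- c(5L, 0L, 2L); y <- c(1L, 4L, 0L)
  s <- make_doublet(x, y, target_size = 1000)
  expect_identical(s, x + y)
  set.seed(1)
  down <- make_doublet(x, y, target_size = 6)
  expect_equal(sum(down), 6)
  expect_true(all(down >= 0))
})

test_that("damaged cells exceed the mitochondrial QC cut by design", {
  sce <- generate_dataset(synthetic_design(n_genes = 400, n_patients = 1,
                                           cells_per_sample = 150,
                                           mito_high_fraction = 0.1,
                                           doublet_rate = 0, seed = 21))
  md <- as.data.frame(SummarizedExperiment::colData(sce))
  qc <- compute_cell_qc(sce)
  expect_gt(mean(qc$mito_fraction[md$true_is_mito_high]), 0.35)
  expect_lt(mean(qc$mito_fraction[!md$true_is_mito_high]), 0.1)
})
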