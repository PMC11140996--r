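test_that("self-referenced noiseless cells center to zero", {
  # every cell identical => each gene equals its reference mean exactly
  counts <- matrix(rep(c(5L, 2L, 8L, 1L, 3L, 9L), 10), nrow = 6)
  sce <- toy_sce(counts)
  rel <- relative_expression(sce, reference_cells = seq_len(10),
                             expression_cutoff = 0)
  expect_lt(max(abs(rel$rel)), 1e-9)
})

test_that("low-expression genes are dropped at the cutoff", {
  counts <- rbind(high = rep(50L, 20), low = rep(0L, 20), mid = rep(10L, 20))
  counts["low", 1] <- 1L
  sce <- toy_sce(counts)
  # with scale 100 means: high ~ 83, low ~ tiny, mid ~ 17
  rel <- relative_expression(sce, reference_cells = 1:20,
                             expression_cutoff = 0.1, scale_factor = 100)
  expect_setequal(rel$genes, c("high", "mid"))
  expect_error(relative_expression(sce, 1:20, expression_cutoff = 1e6),
               "cutoff")
  expect_error(relative_expression(sce, integer(0)), "empty")
})

test_that("centered values are clipped symmetrically", {
  counts <- matrix(c(1000L, rep(1L, 19)), nrow = 1)
  counts <- rbind(counts, matrix(5L, 4, 20))
  sce <- toy_sce(counts)
  rel <- relative_expression(sce, reference_cells = 2:20,
                             expression_cutoff = 0, clip = 3)
  expect_lte(max(rel$rel), 3)
  expect_gte(min(rel$rel), -3)
  expect_equal(max(rel$rel), 3)  # the outlier cell saturates the clip
})

test_that("sliding windows follow the stride-1 and short-chromosome rules", {
  anno1 <- data.frame(gene_id = paste0("g", 1:250), chromosome = "chr1",
                      start_position = 1:250)
  expect_length(sliding_windows(anno1, anno1$gene_id, 100), 151)

  anno2 <- data.frame(gene_id = paste0("g", 1:250),
                      chromosome = rep(c("chr1", "chr2"), c(150, 100)),
                      start_position = c(1:150, 1:100))
  expect_length(sliding_windows(anno2, anno2$gene_id, 100), 52)

  anno3 <- data.frame(gene_id = paste0("g", 1:40), chromosome = "chr1",
                      start_position = 1:40)
  w3 <- sliding_windows(anno3, anno3$gene_id, 100)
  expect_length(w3, 1)
  expect_length(w3[[1]]$genes, 40)

  # windows respect genomic order even when the table is shuffled
  shuf <- anno1[sample(nrow(anno1)), ]
  w <- sliding_windows(shuf, shuf$gene_id, 100)
  expect_equal(w[[1]]$genes, paste0("g", 1:100))
})

test_that("CNVi is the window mean and matches brute force exactly", {
  rel <- matrix(c(0.2, 0.4), nrow = 2,
                dimnames = list(c("g1", "g2"), "c1"))
  wins <- list(list(chromosome = "chr1", genes = c("g1", "g2")))
  prof <- cnv_profile(rel, wins)
  expect_equal(unname(prof$cnv_matrix[1, 1]), 0.3)

  zero <- matrix(0, 5, 3, dimnames = list(paste0("g", 1:5), paste0("c", 1:3)))
  wz <- list(list(chromosome = "chr1", genes = paste0("g", 1:3)),
             list(chromosome = "chr1", genes = paste0("g", 2:4)))
  expect_true(all(cnv_profile(zero, wz)$cnv_matrix == 0))

  expect_error(cnv_profile(rel, list(list(chromosome = "chr1",
                                          genes = c("g1", "gX")))),
               "dropped gene")
})

test_that("pipeline CNV score equals the double-loop oracle to 1e-12", {
  d <- synthetic_design(
    n_genes = 500, n_patients = 1, tissues = "tumor",
    cells_per_sample = 50, n_chromosomes = 2,
    cnv_segments = list(cnv_segment("chr1", 20, 140, copy_ratio = 2.0)),
    cell_type_props = list(tumor = c(epithelial = 1)),
    malignant_fraction = 0.5, doublet_rate = 0, mito_high_fraction = 0,
    seed = 31)
  sce <- generate_dataset(d)
  rel <- relative_expression(sce, reference_cells = seq_len(25))
  wins <- sliding_windows(design_gene_anno(d), rel$genes, 100)
  prof <- cnv_score_and_call(cnv_profile(rel, wins))
  oracle <- brute_force_cnv_score(rel$rel, wins)
  expect_lt(max(abs(prof$cnv_score - oracle)), 1e-12)
})

test_that("the malignancy call is strict at the threshold", {
  cnvi <- rbind(zero = rep(0, 10),
                half = rep(c(0.3, 0), each = 5),
                at = rep(0.25, 10))
  prof <- structure(list(windows = vector("list", 10),
                         cnv_matrix = cnvi),
                    class = "cnv_profile")
  done <- cnv_score_and_call(prof, threshold = 0.04)
  expect_equal(unname(done$cnv_score),
               c(0, 0.5 * 0.09, 0.0625))
  expect_equal(unname(done$is_malignant[c("zero", "half")]), c(FALSE, TRUE))
  # score exactly at the threshold is not called ("above" is strict)
  at_threshold <- cnv_score_and_call(prof, threshold = 0.0625)
  expect_false(at_threshold$is_malignant[["at"]])
})

test_that("reference mean is invariant to duplicating reference cells", {
  sce <- generate_dataset(null_design(seed = 17, n_genes = 200,
                                      cells_per_sample = 30,
                                      tissues = "tumor"))
  cts <- SummarizedExperiment::assay(sce, "counts")
  dup <- cbind(cts, cts[, 1:10])
  colnames(dup) <- c(colnames(cts), paste0("dup", 1:10))
  sce2 <- toy_sce(as.matrix(dup))
  r1 <- relative_expression(toy_sce(as.matrix(cts)), reference_cells = 1:10,
                            expression_cutoff = 0)
  r2 <- relative_expression(sce2, reference_cells = c(1:10, 31:40),
                            expression_cutoff = 0)
  expect_equal(r2$rel[, 1:30], r1$rel, tolerance = 1e-12)
})

test_that("the score does not depend on window ordering", {
  sce <- generate_dataset(null_design(seed = 19, n_genes = 300,
                                      cells_per_sample = 20,
                                      tissues = "tumor"))
  rel <- relative_expression(sce, reference_cells = 1:10)
  wins <- sliding_windows(design_gene_anno(null_design(1, n_genes = 300)),
                          rel$genes, 50)
  p1 <- cnv_score_and_call(cnv_profile(rel, wins))
  p2 <- cnv_score_and_call(cnv_profile(rel, rev(wins)))
  expect_equal(p1$cnv_score, p2$cnv_score, tolerance = 1e-12)
})

test_that("zero windows raise an error", {
  prof <- structure(list(windows = list(),
                         cnv_matrix = matrix(0, 2, 0)),
                    class = "cnv_profile")
  expect_error(cnv_score_and_call(prof), "zero windows")
})
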