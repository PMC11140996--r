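test_that("gene-set scores are means with linear composition", {
  set.seed(2)
  counts <- matrix(rpois(400, 5), nrow = 20)
  sce <- toy_sce(counts)
  g1 <- paste0("G", 1:4); g2 <- paste0("G", 11:16)
  s1 <- score_gene_set(sce, g1)
  s2 <- score_gene_set(sce, g2)
  s12 <- score_gene_set(sce, c(g1, g2))
  expect_equal(s12, (4 * s1 + 6 * s2) / 10, tolerance = 1e-12)

  # all-zero cell scores zero
  counts0 <- counts; counts0[, 3] <- 0L
  expect_equal(unname(score_gene_set(toy_sce(counts0), g1)[3]), 0)

  expect_warning(score_gene_set(sce, c(g1, "NOPE")), "absent")
  expect_error(suppressWarnings(score_gene_set(sce, "NOPE")), "no gene")
})

test_that("context sets recover the planted programs and order by tissue", {
  r <- benchmark_context_recovery(seed = 2)
  expect_true(all(r$recovery >= 0.9))
  for (nm in names(r$sets)) {
    planted <- r$planted[[c(nontumor_activating = "nontumor_shared",
                            tissue_residing = "tissue_shared",
                            tumor_modifying = "tumor_specific")[[nm]]]]
    expect_true(all(r$sets[[nm]] %in% planted))
    expect_lte(length(r$sets[[nm]]), 21)
  }
  # the tumor-modifying score singles out tumor; the nontumor-activating
  # score is high in both non-tumor compartments and low in tumor
  tm <- r$mean_tumor_modifying
  expect_gt(tm[["tumor"]], tm[["peritumor"]])
  expect_gt(tm[["tumor"]], tm[["blood"]])
  na <- r$mean_nontumor_activating
  expect_gt(na[["blood"]], na[["tumor"]])
  expect_gt(na[["peritumor"]], na[["tumor"]])
  tr <- r$mean_tissue_residing
  expect_gt(tr[["peritumor"]], tr[["blood"]])
  expect_gt(tr[["tumor"]], tr[["blood"]])
})

test_that("context construction ignores cell and gene order", {
  d <- synthetic_design(
    n_genes = 500, n_patients = 1, cells_per_sample = 120,
    n_chromosomes = 3,
    cell_type_props = list(blood = c(neutrophil = 1),
                           peritumor = c(neutrophil = 1),
                           tumor = c(neutrophil = 1)),
    programs = list(
      gene_program("nt", paste0("G", seq(1, 57, 4)),
                   c("blood", "peritumor"), 2),
      gene_program("ts", paste0("G", seq(2, 58, 4)),
                   c("peritumor", "tumor"), 2),
      gene_program("tm", paste0("G", seq(3, 59, 4)), "tumor", 2)),
    doublet_rate = 0, mito_high_fraction = 0, seed = 41)
  sce <- generate_dataset(d)
  cts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  tissue <- as.data.frame(SummarizedExperiment::colData(sce))$tissue
  a <- build_context_scores(cts, tissue_labels = tissue, top_n = 10)
  set.seed(1)
  pc <- sample(ncol(cts)); pg <- sample(nrow(cts))
  b <- build_context_scores(cts[pg, pc], tissue_labels = tissue[pc],
                            top_n = 10)
  for (nm in names(a$sets)) {
    expect_setequal(a$sets[[nm]], b$sets[[nm]])
  }
  # prefix property of the fold-change ranking
  big <- build_context_scores(cts, tissue_labels = tissue, top_n = 21)
  for (nm in names(a$sets)) {
    expect_true(all(a$sets[[nm]] %in% big$sets[[nm]]))
  }
})

test_that("a null design yields no separable context signal", {
  sce <- generate_dataset(null_design(seed = 29, n_genes = 400,
                                      cells_per_sample = 100))
  suppressWarnings(cs <- build_context_scores(sce))
  # either no genes pass the double gate at all, or the few chance
  # survivors carry no tissue information when scored on an independent
  # replicate (scoring the discovery data itself would inherit the
  # selection bias of the significance gate)
  replicate_sce <- generate_dataset(null_design(seed = 30, n_genes = 400,
                                                cells_per_sample = 100))
  rep_tissue <- as.data.frame(
    SummarizedExperiment::colData(replicate_sce))$tissue
  for (nm in names(cs$sets)) {
    if (length(cs$sets[[nm]]) == 0) {
      expect_true(all(cs$scores[[nm]] == 0))
    } else {
      s <- score_gene_set(replicate_sce, cs$sets[[nm]])
      p <- summary(stats::aov(s ~ factor(rep_tissue)))[[1]][1, "Pr(>F)"]
      expect_gt(p, 0.01)
    }
  }
})

test_that("tissue mapping pools adjacent compartments", {
  d <- synthetic_design(
    n_genes = 300, n_patients = 1,
    tissues = c("blood", "liver", "gb", "tumor"),
    cells_per_sample = 60, n_chromosomes = 3,
    cell_type_props = list(blood = c(neutrophil = 1),
                           liver = c(neutrophil = 1),
                           gb = c(neutrophil = 1),
                           tumor = c(neutrophil = 1)),
    doublet_rate = 0, mito_high_fraction = 0, seed = 3)
  sce <- generate_dataset(d)
  suppressWarnings(
    cs <- build_context_scores(
      sce, tissue_map = c(liver = "peritumor", gb = "peritumor")))
  expect_setequal(unique(cs$scores$tissue),
                  c("blood", "peritumor", "tumor"))
  expect_error(build_context_scores(sce), "three classes")
})

test_that("anchored signatures unite DEG and correlation arms", {
  # two planted "subtype" programs: the anchor's module and an LI-up module
  anchor <- "G1"
  module <- paste0("G", seq(1, 37, 4))     # 10 genes co-active with anchor
  li_up <- paste0("G", seq(3, 47, 4))      # 12 genes up in the LI subtype
  d <- synthetic_design(
    n_genes = 400, n_patients = 1, tissues = c("li", "lo"),
    cells_per_sample = 250, n_chromosomes = 3,
    cell_type_props = list(li = c(epithelial = 1), lo = c(epithelial = 1)),
    programs = list(gene_program("anchor_module", module, "li", 2),
                    gene_program("li_program", li_up, "li", 2)),
    doublet_rate = 0, mito_high_fraction = 0, seed = 15)
  sce <- generate_dataset(d)
  tissue <- as.data.frame(SummarizedExperiment::colData(sce))$tissue
  sig <- build_signature(sce, tissue, anchor, contrast = c("li", "lo"))
  planted <- union(module, li_up)
  expect_gte(mean(planted %in% sig$genes), 0.9)
  expect_true(anchor %in% sig$genes)

  # unattainable correlation leaves only the DEG arm plus the anchor
  sig1 <- build_signature(sce, tissue, anchor, contrast = c("li", "lo"),
                          corr_threshold = 1.0)
  expect_setequal(sig1$genes,
                  union(sig1$construction$deg_arm, anchor))

  # constant anchor: correlation arm contributes nothing, with a warning
  cts <- as.matrix(SummarizedExperiment::assay(sce, "counts"))
  cts["G390", ] <- 0L  # zero everywhere: constant after normalization
  expect_warning(
    sig2 <- build_signature(toy_sce(cts), tissue, "G390",
                            contrast = c("li", "lo")),
    "constant")
  expect_length(sig2$construction$corr_arm, 0)

  expect_error(build_signature(sce, tissue, "NOPE", c("li", "lo")),
               "anchor")
})
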