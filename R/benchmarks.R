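#' Validation experiments with planted truth
#'
#' Each `benchmark_*` function builds a synthetic dataset whose truth is
#' known, runs the corresponding analysis exactly as a user would, and
#' returns the recovery metrics. They are the package's standing
#' validation suite: the tests assert on them and the acceptance script
#' reports them.
#'
#' `benchmark_malignancy()` plants one 330-gene copy-ratio-2.0 gain on a
#' compact three-autosome genome (1200 genes) carried by half of 200 tumor
#' epithelial cells, with 200 normal peritumor epithelial cells as
#' reference, and measures sensitivity and specificity of the malignancy
#' call at the default threshold 0.04. The compact genome is deliberate:
#' the mean-of-squared-windows score scales with the fraction of windows
#' inside altered regions, and the 0.04 cut corresponds to the extensive
#' aneuploidy of real tumor genomes, so the planted gain must occupy a
#' realistic fraction of the genome rather than a sliver of a large quiet
#' one.
#'
#' @param seed integer seed for the experiment.
#' @return list of metrics; see each function's value section.
#' @name benchmarks
NULL

#' @rdname benchmarks
#' @param threshold malignancy threshold on the CNV score.
#' @export
benchmark_malignancy <- function(seed = 1L, threshold = 0.04) {
  design <- synthetic_design(
    n_genes = 1200, n_patients = 1, tissues = c("peritumor", "tumor"),
    cells_per_sample = 200, n_chromosomes = 3,
    cnv_segments = list(cnv_segment("chr1", 31, 360, copy_ratio = 2.0)),
    cell_type_props = list(peritumor = c(epithelial = 1),
                           tumor = c(epithelial = 1)),
    malignant_fraction = 0.5, doublet_rate = 0, mito_high_fraction = 0,
    seed = seed)
  sce <- generate_dataset(design)
  md <- .get_cell_meta(sce)
  ref <- md$cell_id[md$tissue == "peritumor"]
  prof <- call_malignant(sce, ref, threshold = threshold)
  truth <- md$true_is_malignant
  list(sensitivity = mean(prof$is_malignant[truth]),
       specificity = mean(!prof$is_malignant[!truth]),
       n_cells = length(truth), n_malignant_true = sum(truth),
       mean_score_malignant = mean(prof$cnv_score[truth]),
       mean_score_normal = mean(prof$cnv_score[!truth]),
       profile = prof, truth = truth)
}

#' @rdname benchmarks
#' @param n_genes null genes simulated.
#' @param n_per_group cells per group.
#' @param alpha nominal level the empirical type-I error is measured at.
#' @param mix_alpha,mix_mean,mix_sd detection rate, mean and sd of the
#'   null zero/normal expression mixture both groups are drawn from.
#' @export
benchmark_bimod_type1 <- function(seed = 1L, n_genes = 10000,
                                  n_per_group = 50, alpha = 0.001,
                                  mix_alpha = 0.7, mix_mean = 1.5,
                                  mix_sd = 0.5) {
  set.seed(seed)
  draw <- function() {
    v <- numeric(n_per_group)
    on <- runif(n_per_group) < mix_alpha
    v[on] <- abs(stats::rnorm(sum(on), mix_mean, mix_sd)) + 1e-6
    v
  }
  p <- vapply(seq_len(n_genes),
              function(i) bimod_lrt(draw(), draw())$p_value, 0)
  k <- sum(p < alpha)
  ci <- alpha + c(-1, 1) * 1.96 * sqrt(alpha * (1 - alpha) / n_genes)
  list(empirical_type1 = k / n_genes, n_rejections = k, n_genes = n_genes,
       nominal = alpha, ci_lower = max(ci[1], 0), ci_upper = ci[2],
       within_ci = k / n_genes >= max(ci[1], 0) & k / n_genes <= ci[2])
}

#' @rdname benchmarks
#' @param top_n context-set size (default 21).
#' @param log2_effect,program_size,cells_per_tissue planted-program
#'   conditions of the recovery experiment.
#' @export
benchmark_context_recovery <- function(seed = 1L, top_n = 21,
                                       log2_effect = 2, program_size = 30,
                                       cells_per_tissue = 300) {
  design <- synthetic_design(
    n_genes = 2000, n_patients = 1,
    cells_per_sample = cells_per_tissue,
    cell_type_props = list(blood = c(neutrophil = 1),
                           peritumor = c(neutrophil = 1),
                           tumor = c(neutrophil = 1)),
    programs = .three_programs(log2_effect, program_size),
    doublet_rate = 0, mito_high_fraction = 0, seed = seed)
  sce <- generate_dataset(design)
  cs <- build_context_scores(sce, top_n = top_n)
  planted <- lapply(design$programs, `[[`, "genes")
  names(planted) <- vapply(design$programs, `[[`, "", "name")
  pairing <- c(nontumor_activating = "nontumor_shared",
               tissue_residing = "tissue_shared",
               tumor_modifying = "tumor_specific")
  recovery <- vapply(names(pairing), function(nm) {
    truth <- planted[[pairing[[nm]]]]
    got <- cs$sets[[nm]]
    if (length(got) == 0) return(0)
    sum(got %in% truth) / min(top_n, length(truth))
  }, 0)
  mean_by_tissue <- function(col) {
    vapply(split(cs$scores[[col]], cs$scores$tissue), mean, 0)
  }
  list(recovery = recovery, sets = cs$sets, planted = planted,
       mean_tumor_modifying = mean_by_tissue("tumor_modifying"),
       mean_nontumor_activating = mean_by_tissue("nontumor_activating"),
       mean_tissue_residing = mean_by_tissue("tissue_residing"),
       context = cs)
}

# the standard three disjoint neutrophil programs on the 2000-gene genome
#' @noRd
.three_programs <- function(log2_effect, program_size) {
  base <- synthetic_design(n_genes = 2000)
  anno <- design_gene_anno(base)
  auto <- anno$gene_id[!anno$is_mitochondrial]
  by <- max(3L, (length(auto) - 10L) %/% program_size)
  pick <- function(offset) auto[seq(offset, by = by,
                                    length.out = program_size)]
  list(
    gene_program("nontumor_shared", pick(1), c("blood", "peritumor"),
                 log2_effect, cell_types = "neutrophil"),
    gene_program("tissue_shared", pick(5), c("peritumor", "tumor"),
                 log2_effect, cell_types = "neutrophil"),
    gene_program("tumor_specific", pick(9), "tumor",
                 log2_effect, cell_types = "neutrophil"))
}

#' @rdname benchmarks
#' @param doublet_rate planted doublet rate of the consensus experiment.
#' @export
benchmark_doublet_consensus <- function(seed = 1L, doublet_rate = 0.1) {
  # two well-separated cell types in one sample so doublets sit between them
  design <- synthetic_design(
    n_genes = 1000, n_patients = 1, tissues = "tumor",
    cells_per_sample = 500, n_chromosomes = 3,
    cell_type_props = list(tumor = c(neutrophil = 0.5, epithelial = 0.5)),
    programs = list(
      gene_program("neu_identity", paste0("G", 1:40), "tumor", 3,
                   cell_types = "neutrophil"),
      gene_program("epi_identity", paste0("G", 41:80), "tumor", 3,
                   cell_types = "epithelial")),
    doublet_rate = doublet_rate, mito_high_fraction = 0, seed = seed)
  sce <- generate_dataset(design)
  md <- .get_cell_meta(sce)
  scores <- lapply(1:3, function(i) {
    score_doublets_simulated(sce, k_neighbors = c(15L, 20L, 25L)[i],
                             seed = seed + 100L + i)
  })
  cons <- consensus_doublet_call(scores, thresholds = 0.5, min_votes = 2)
  truth <- md$true_is_doublet
  list(recall = mean(cons$is_doublet[truth]),
       specificity = mean(!cons$is_doublet[!truth]),
       n_doublets_true = sum(truth), n_cells = length(truth),
       mean_score_doublet = mean(scores[[2]][truth]),
       mean_score_singlet = mean(scores[[2]][!truth]))
}
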