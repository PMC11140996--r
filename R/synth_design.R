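#' Planted gene program
#'
#' A set of genes jointly upregulated (by `2^log2_effect`) in the cells of
#' the listed tissues, optionally restricted to given cell types. Programs
#' are the planted truth behind tissue-specific transcriptional states:
#' downstream differential expression and context-score construction are
#' validated by recovering them.
#'
#' @param name program label, e.g. "tumor_specific".
#' @param genes character vector of gene ids (see [design_gene_anno()] for
#'   the ids a design generates).
#' @param active_tissues tissues in which the program is on.
#' @param log2_effect positive log2 fold change applied to the genes'
#'   negative-binomial means in active tissues.
#' @param cell_types cell types the program applies to, or `NULL` for all.
#' @return a `gene_program` object.
#' @export
gene_program <- function(name, genes, active_tissues, log2_effect,
                         cell_types = NULL) {
  .check(is.character(name) && length(name) == 1, "program name must be a string")
  .check(length(genes) > 0, "program '", name, "' has an empty gene set")
  .check(is.numeric(log2_effect) && log2_effect > 0,
         "program '", name, "' needs log2_effect > 0")
  .check(length(active_tissues) > 0, "program '", name, "' has no active tissues")
  structure(list(name = name, genes = as.character(genes),
                 active_tissues = as.character(active_tissues),
                 log2_effect = log2_effect, cell_types = cell_types),
            class = "gene_program")
}

#' Planted copy-number segment
#'
#' A contiguous run of genes on one chromosome whose expression means are
#' multiplied by `copy_ratio` in malignant cells. Gene indices are 1-based
#' positions within the chromosome's genomic gene order.
#'
#' @param chromosome chromosome label, e.g. "chr2".
#' @param start_gene_index,end_gene_index first/last gene of the segment
#'   (inclusive), with start < end.
#' @param copy_ratio positive multiplier; 2 = one extra copy of a diploid
#'   locus, 0.5 = one-copy loss. Must differ from 1.
#' @return a `cnv_segment` object.
#' @export
cnv_segment <- function(chromosome, start_gene_index, end_gene_index,
                        copy_ratio) {
  .check(start_gene_index >= 1 && start_gene_index < end_gene_index,
         "cnv segment needs 1 <= start < end")
  .check(copy_ratio > 0 && copy_ratio != 1,
         "copy_ratio must be positive and different from 1")
  structure(list(chromosome = chromosome,
                 start_gene_index = as.integer(start_gene_index),
                 end_gene_index = as.integer(end_gene_index),
                 copy_ratio = copy_ratio),
            class = "cnv_segment")
}

#' Synthetic multi-tissue scRNA-seq design
#'
#' Full parameterization of the simulator: a synthetic genome, per-gene
#' negative-binomial baselines, planted tissue programs, planted copy-number
#' segments carried by a fraction of tumor epithelial cells, doublets, and a
#' subpopulation of damaged high-mitochondrial cells. [generate_dataset()]
#' turns a design into a count matrix; identical designs (including `seed`)
#' give bit-identical data.
#'
#' @param n_genes total number of genes, mitochondrial genes included.
#' @param n_patients number of patients; every patient contributes one
#'   sample per tissue.
#' @param tissues tissue labels.
#' @param cells_per_sample singlet cells per patient x tissue sample.
#' @param baseline_log_mean,baseline_log_sd parameters of the log-normal
#'   law the per-gene baseline NB means are drawn from.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); one value shared by all genes.
#' @param n_chromosomes autosome-like contigs the non-mitochondrial genes
#'   are spread over (mitochondrial genes sit on their own "chrM").
#' @param programs list of [gene_program()] objects; gene sets must be
#'   disjoint from each other and from mitochondrial genes.
#' @param cnv_segments list of [cnv_segment()] objects.
#' @param cell_type_props named list: tissue -> named numeric vector of
#'   cell-type proportions (must sum to 1).
#' @param malignant_fraction fraction of epithelial cells in the
#'   `malignant_tissues` that carry the planted copy-number segments.
#' @param malignant_tissues tissues whose epithelial cells can be malignant.
#' @param doublet_rate doublets added per sample, as a fraction of
#'   `cells_per_sample`.
#' @param mito_gene_fraction fraction of genes placed on chrM and flagged
#'   mitochondrial.
#' @param mito_high_fraction fraction of cells simulated as damaged.
#' @param mito_high_target expected mitochondrial count fraction in damaged
#'   cells (> 0.35 so they land past the 30% QC cut).
#' @param seed integer seed; the single source of randomness.
#' @return a validated `synthetic_design` object.
#' @seealso [default_design()] for the standard three-tissue configuration.
#' @export
synthetic_design <- function(n_genes = 2000,
                             n_patients = 3,
                             tissues = c("blood", "peritumor", "tumor"),
                             cells_per_sample = 300,
                             baseline_log_mean = log(0.5),
                             baseline_log_sd = 1,
                             nb_dispersion = 0.3,
                             n_chromosomes = 5,
                             programs = list(),
                             cnv_segments = list(),
                             cell_type_props = NULL,
                             malignant_fraction = 0.5,
                             malignant_tissues = "tumor",
                             doublet_rate = 0.05,
                             mito_gene_fraction = 0.025,
                             mito_high_fraction = 0.05,
                             mito_high_target = 0.5,
                             seed = 1L) {
  if (is.null(cell_type_props)) {
    cell_type_props <- lapply(tissues, function(tt) {
      if (tt == "blood") c(neutrophil = 1) else c(neutrophil = 0.5, epithelial = 0.5)
    })
    names(cell_type_props) <- tissues
  }
  design <- structure(
    list(n_genes = as.integer(n_genes), n_patients = as.integer(n_patients),
         tissues = tissues, cells_per_sample = as.integer(cells_per_sample),
         baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
         nb_dispersion = nb_dispersion, n_chromosomes = as.integer(n_chromosomes),
         programs = programs, cnv_segments = cnv_segments,
         cell_type_props = cell_type_props,
         malignant_fraction = malignant_fraction,
         malignant_tissues = malignant_tissues,
         doublet_rate = doublet_rate,
         mito_gene_fraction = mito_gene_fraction,
         mito_high_fraction = mito_high_fraction,
         mito_high_target = mito_high_target,
         seed = as.integer(seed)),
    class = "synthetic_design")
  validate_design(design)
  design
}

#' Gene annotation implied by a design
#'
#' Lays out the synthetic genome deterministically from the design's size
#' parameters: the first `ceiling(mito_gene_fraction * n_genes)` genes are
#' mitochondrial ("MT-1", ...) on their own contig "chrM"; the remaining
#' genes ("G1", ...) are split into contiguous, evenly sized blocks over
#' "chr1" .. "chrK" with evenly spaced start positions.
#'
#' @param design a `synthetic_design`.
#' @return data.frame with gene_id, chromosome, start_position,
#'   is_mitochondrial — one row per gene, in matrix row order.
#' @export
design_gene_anno <- function(design) {
  n_mito <- ceiling(design$mito_gene_fraction * design$n_genes)
  n_auto <- design$n_genes - n_mito
  .check(n_auto > 0, "design has no non-mitochondrial genes")
  chr_of <- rep(paste0("chr", seq_len(design$n_chromosomes)),
                each = ceiling(n_auto / design$n_chromosomes))[seq_len(n_auto)]
  pos <- unlist(lapply(split(seq_len(n_auto), factor(chr_of, unique(chr_of))),
                       function(ii) seq_along(ii) * 1e5), use.names = FALSE)
  data.frame(
    gene_id = c(if (n_mito > 0) paste0("MT-", seq_len(n_mito)),
                paste0("G", seq_len(n_auto))),
    chromosome = c(rep("chrM", n_mito), chr_of),
    start_position = c(seq_len(n_mito) * 1e3, pos),
    is_mitochondrial = rep(c(TRUE, FALSE), c(n_mito, n_auto)),
    stringsAsFactors = FALSE)
}

#' @noRd
validate_design <- function(design) {
  d <- design
  .check(d$n_genes > 0 && d$n_patients > 0 && d$cells_per_sample > 0 &&
           d$n_chromosomes > 0, "all design counts must be positive")
  for (f in c("malignant_fraction", "doublet_rate", "mito_gene_fraction",
              "mito_high_fraction")) {
    .check(d[[f]] >= 0 && d[[f]] <= 1, f, " must lie in [0, 1]")
  }
  .check(d$nb_dispersion > 0, "nb_dispersion must be positive")
  .check(anyDuplicated(d$tissues) == 0, "duplicated tissue labels")
  .check(setequal(names(d$cell_type_props), d$tissues),
         "cell_type_props must name every tissue exactly once")
  for (tt in d$tissues) {
    p <- d$cell_type_props[[tt]]
    .check(abs(sum(p) - 1) < 1e-8 && all(p >= 0),
           "cell-type proportions for ", tt, " must be non-negative and sum to 1")
  }
  anno <- design_gene_anno(d)
  seen <- character(0)
  for (pr in d$programs) {
    .check(inherits(pr, "gene_program"), "programs must be gene_program objects")
    .check(all(pr$active_tissues %in% d$tissues),
           "program '", pr$name, "' references tissue(s) absent from the design")
    .check(all(pr$genes %in% anno$gene_id[!anno$is_mitochondrial]),
           "program '", pr$name,
           "' references unknown or mitochondrial gene ids")
    .check(!any(pr$genes %in% seen),
           "program gene sets overlap (program '", pr$name, "')")
    seen <- c(seen, pr$genes)
  }
  chr_sizes <- table(anno$chromosome[!anno$is_mitochondrial])
  for (seg in d$cnv_segments) {
    .check(inherits(seg, "cnv_segment"), "cnv_segments must be cnv_segment objects")
    .check(seg$chromosome %in% names(chr_sizes),
           "cnv segment on unknown chromosome ", seg$chromosome)
    .check(seg$end_gene_index <= chr_sizes[[seg$chromosome]],
           "cnv segment exceeds ", seg$chromosome, " (",
           chr_sizes[[seg$chromosome]], " genes)")
  }
  .check(length(d$cnv_segments) == 0 ||
           all(d$malignant_tissues %in% d$tissues),
         "malignant_tissues must be design tissues")
  invisible(design)
}

#' Standard three-tissue study design
#'
#' The default configuration used by the demo pipeline and the validation
#' suite: 3 patients x {blood, peritumor, tumor} x 300 cells, 2000 genes on
#' 5 chromosomes plus chrM, three disjoint 30-gene neutrophil programs at
#' log2 effect 2 (blood+peritumor shared, peritumor+tumor shared, tumor
#' specific), one 300-gene copy-ratio-2 gain on chr2 carried by half of the
#' tumor epithelial cells, 5% doublets and 5% damaged high-mito cells.
#'
#' @param seed integer seed passed through to the design.
#' @param log2_effect effect size shared by the three planted programs.
#' @param program_size genes per planted program.
#' @return a `synthetic_design`.
#' @export
default_design <- function(seed = 1L, log2_effect = 2, program_size = 30) {
  programs <- .three_programs(log2_effect, program_size)
  segs <- list(cnv_segment("chr2", 30, 329, copy_ratio = 2.0))
  synthetic_design(programs = programs, cnv_segments = segs, seed = seed)
}

#' @export
print.synthetic_design <- function(x, ...) {
  cat("synthetic_design:", x$n_genes, "genes,", x$n_patients, "patients x",
      length(x$tissues), "tissues x", x$cells_per_sample, "cells\n")
  cat("  tissues:", paste(x$tissues, collapse = ", "), "\n")
  cat("  programs:", length(x$programs), "| cnv segments:",
      length(x$cnv_segments), "| seed:", x$seed, "\n")
  invisible(x)
}
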