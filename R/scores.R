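#' Mean-expression score over a gene set
#'
#' The per-cell score is the mean log-normalized expression over the set's
#' genes; the "average expression" scoring used for functional signatures
#' and for the context-dependent scores. Genes absent from the matrix are
#' dropped with a warning; `z_score = TRUE` standardizes each gene across
#' cells before averaging.
#'
#' @param data SingleCellExperiment or counts matrix.
#' @param genes character vector of gene ids.
#' @param z_score standardize genes before averaging (default FALSE: plain
#'   average expression).
#' @param scale_factor library size for normalization.
#' @return named numeric per-cell score.
#' @export
score_gene_set <- function(data, genes, z_score = FALSE, scale_factor = 1e4) {
  counts <- .get_counts(data)
  present <- intersect(genes, rownames(counts))
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present),
            " gene(s) of the set absent from the matrix; dropped")
  }
  .check(length(present) > 0, "no gene of the set is present in the matrix")
  ln <- as.matrix(log_normalize(counts, scale_factor = scale_factor))
  m <- ln[present, , drop = FALSE]
  if (z_score) {
    mu <- rowMeans(m)
    sdv <- apply(m, 1, sd)
    sdv[sdv == 0] <- 1
    m <- (m - mu) / sdv
  }
  colMeans(m)
}

#' Context-dependent neutrophil activation scores
#'
#' Builds the three context scores from a neutrophil count matrix spanning
#' blood, peritumor and tumor cells. Six directional DEG lists come from
#' three two-group contrasts; each score's gene set is the intersection of
#' its two defining "up" lists, ranked by the primary contrast's fold
#' change and truncated to `top_n`:
#' \describe{
#'   \item{nontumor_activating}{up in peritumor vs tumor AND up in blood vs
#'     tumor (shared non-tumor signature; primary ranking peritumor vs
#'     tumor)}
#'   \item{tissue_residing}{up in peritumor vs blood AND up in tumor vs
#'     blood (shared tissue signature; primary ranking peritumor vs blood)}
#'   \item{tumor_modifying}{up in tumor vs peritumor AND up in tumor vs
#'     blood (tumor-specific signature; primary ranking tumor vs
#'     peritumor)}
#' }
#' Per-cell scores are mean log-normalized expression over each set. An
#' empty intersection yields an empty set and all-zero scores with a
#' warning.
#'
#' @param data SingleCellExperiment or counts matrix of neutrophils only.
#' @param tissue_labels per-cell labels; taken from `colData(data)$tissue`
#'   when omitted. Values must map onto blood / peritumor / tumor via
#'   `tissue_map`.
#' @param tissue_map named character vector mapping raw labels to the three
#'   classes, e.g. `c(liver = "peritumor", gb = "peritumor")`; labels
#'   already named blood/peritumor/tumor pass through.
#' @param top_n genes kept per score (default 21).
#' @param fc_threshold,p_threshold significance gates for the underlying
#'   DEG lists (defaults 1.2 and 0.001).
#' @param test DEG test passed to [find_degs()].
#' @param rank_by "fc" (default) ranks intersected genes by the primary
#'   contrast's fold change; "p" by its p-value.
#' @param z_score forwarded to [score_gene_set()].
#' @return a `context_score_set`: list with `sets` (three gene-id
#'   vectors), `scores` (cell x 3 data.frame), `provenance` (the three DEG
#'   tables) and `params`.
#' @export
build_context_scores <- function(data, tissue_labels = NULL,
                                 tissue_map = NULL, top_n = 21,
                                 fc_threshold = 1.2, p_threshold = 0.001,
                                 test = "bimod", rank_by = c("fc", "p"),
                                 z_score = FALSE) {
  rank_by <- match.arg(rank_by)
  counts <- .get_counts(data)
  if (is.null(tissue_labels)) tissue_labels <- .get_cell_meta(data)$tissue
  .check(length(tissue_labels) == ncol(counts),
         "tissue_labels length must match cell count")
  cls <- as.character(tissue_labels)
  if (!is.null(tissue_map)) {
    mapped <- tissue_map[cls]
    cls[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  .check(all(c("blood", "peritumor", "tumor") %in% cls),
         "all three classes (blood, peritumor, tumor) must be present")

  deg <- function(a, b) find_degs(counts, cls, c(a, b),
                                  fc_threshold = fc_threshold,
                                  p_threshold = p_threshold, test = test)
  pvt <- deg("peritumor", "tumor")
  bvt <- deg("blood", "tumor")
  pvb <- deg("peritumor", "blood")

  up <- function(tab) tab$gene_id[tab$significant]
  # "up in B vs A" read off the (A, B) table by symmetry of the test
  dn <- function(tab, fc = fc_threshold, p = p_threshold) {
    tab$gene_id[1 / tab$fold_change > fc & tab$p_value < p]
  }
  pick <- function(candidates, primary, flip = FALSE) {
    tab <- primary[primary$gene_id %in% candidates, , drop = FALSE]
    key <- if (flip) 1 / tab$fold_change else tab$fold_change
    ord <- if (rank_by == "fc") order(-key, tab$p_value)
           else order(tab$p_value, -key)
    utils::head(tab$gene_id[ord], top_n)
  }
  sets <- list(
    nontumor_activating = pick(intersect(up(pvt), up(bvt)), pvt),
    tissue_residing = pick(intersect(up(pvb), dn(bvt)), pvb),
    tumor_modifying = pick(intersect(dn(pvt), dn(bvt)), pvt, flip = TRUE))

  ln_scores <- lapply(names(sets), function(nm) {
    if (length(sets[[nm]]) == 0) {
      warning("empty gene set for ", nm, "; score set to 0")
      setNames(rep(0, ncol(counts)), colnames(counts))
    } else {
      score_gene_set(counts, sets[[nm]], z_score = z_score)
    }
  })
  names(ln_scores) <- names(sets)
  structure(list(
    sets = sets,
    scores = data.frame(cell_id = colnames(counts), tissue = cls,
                        as.data.frame(ln_scores), stringsAsFactors = FALSE),
    provenance = list(peritumor_vs_tumor = pvt, blood_vs_tumor = bvt,
                      peritumor_vs_blood = pvb),
    params = list(top_n = top_n, fc_threshold = fc_threshold,
                  p_threshold = p_threshold, test = test,
                  rank_by = rank_by, z_score = z_score)),
    class = "context_score_set")
}

#' @export
print.context_score_set <- function(x, ...) {
  cat("context_score_set over", nrow(x$scores), "cells\n")
  for (nm in names(x$sets)) {
    cat(" ", nm, ":", length(x$sets[[nm]]), "genes\n")
  }
  invisible(x)
}

#' Data-driven anchored gene signature
#'
#' Builds a signature the way the KRT17 tumor-cell signature is built:
#' significant DEGs up in subtype A versus subtype B, united with genes
#' whose Pearson correlation to an anchor gene (across the supplied cells,
#' on log-normalized expression) exceeds `corr_threshold`, plus the anchor
#' itself. A constant anchor leaves the correlation arm empty with a
#' warning.
#'
#' @param data SingleCellExperiment or counts matrix (typically malignant
#'   cells of both subtypes).
#' @param subtype_labels per-cell labels holding both contrast levels.
#' @param anchor_gene gene the correlation arm is anchored on (e.g.
#'   "KRT17"); must be present.
#' @param contrast length-2 vector `c(A, B)`; DEG arm keeps genes up in A.
#' @param corr_threshold strict lower bound on Pearson correlation
#'   (default 0.3).
#' @param fc_threshold,p_threshold,test DEG gates, as in [find_degs()].
#' @return a `gene_signature`: list with `name`, `genes`, and a `construction`
#'   record (contrast, anchor, threshold, per-arm gene lists).
#' @export
build_signature <- function(data, subtype_labels, anchor_gene, contrast,
                            corr_threshold = 0.3, fc_threshold = 1.2,
                            p_threshold = 0.001, test = "bimod") {
  counts <- .get_counts(data)
  .check(anchor_gene %in% rownames(counts),
         "anchor gene '", anchor_gene, "' absent from the matrix")
  degs <- find_degs(counts, subtype_labels, contrast,
                    fc_threshold = fc_threshold, p_threshold = p_threshold,
                    test = test)
  deg_arm <- degs$gene_id[degs$significant]

  ln <- as.matrix(log_normalize(counts))
  anchor <- ln[anchor_gene, ]
  if (sd(anchor) == 0) {
    warning("anchor gene is constant across cells; ",
            "correlation arm contributes no genes")
    corr_arm <- character(0)
    corr <- NULL
  } else {
    corr <- suppressWarnings(as.vector(cor(t(ln), anchor)))
    names(corr) <- rownames(ln)
    corr_arm <- names(corr)[!is.na(corr) & corr > corr_threshold]
    corr_arm <- setdiff(corr_arm, anchor_gene)
  }
  structure(list(
    name = paste0(anchor_gene, "_signature"),
    genes = union(union(deg_arm, corr_arm), anchor_gene),
    construction = list(contrast = contrast, anchor_gene = anchor_gene,
                        corr_threshold = corr_threshold,
                        deg_arm = deg_arm, corr_arm = corr_arm)),
    class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("signature", x$name, "with", length(x$genes), "genes (",
      length(x$construction$deg_arm), "DEG arm,",
      length(x$construction$corr_arm), "correlation arm )\n")
  invisible(x)
}
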