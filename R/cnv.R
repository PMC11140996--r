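#' Reference-centered relative expression for CNV inference
#'
#' Prepares the matrix the sliding-window CNV profile is computed from:
#' mitochondrial-contig genes are excluded, genes whose mean normalized
#' expression across all cells falls below `expression_cutoff` are dropped,
#' the rest are log-normalized (fixed library size, `log(x+1)`), centered
#' per gene on the mean over the reference cells (a set of normal
#' epithelial cells), and clipped to `[-clip, clip]`.
#'
#' @param data SingleCellExperiment with gene annotation.
#' @param reference_cells cell ids (or logical/integer index) of the normal
#'   reference cells; may overlap the query cells.
#' @param expression_cutoff minimum mean normalized expression for a gene
#'   to be retained (default 0.1).
#' @param clip symmetric bound on centered values (default 3).
#' @param scale_factor library size for normalization (default 10000).
#' @return list with `rel` (retained gene x cell dense matrix of centered,
#'   clipped values), `genes` (retained gene ids) and `reference_cells`
#'   (resolved ids).
#' @export
relative_expression <- function(data, reference_cells,
                                expression_cutoff = 0.1, clip = 3,
                                scale_factor = 1e4) {
  counts <- .get_counts(data)
  anno <- .get_gene_anno(data)
  ref <- .resolve_cells(reference_cells, colnames(counts))
  .check(length(ref) > 0, "reference cell set is empty")

  keep_chr <- !anno$is_mitochondrial & anno$chromosome != "chrM"
  counts <- counts[keep_chr, , drop = FALSE]
  lib <- Matrix::colSums(.get_counts(data))  # full library incl. chrM genes
  lib[lib == 0] <- 1
  norm <- counts %*% Matrix::Diagonal(ncol(counts), scale_factor / lib)
  keep <- Matrix::rowMeans(norm) >= expression_cutoff
  .check(any(keep), "no genes survive the expression cutoff")
  ln <- norm[keep, , drop = FALSE]
  ln@x <- log1p(ln@x)
  ln <- as.matrix(ln)
  rownames(ln) <- rownames(counts)[keep]
  colnames(ln) <- colnames(counts)

  center <- rowMeans(ln[, ref, drop = FALSE])
  rel <- ln - center
  rel[rel > clip] <- clip
  rel[rel < -clip] <- -clip
  list(rel = rel, genes = rownames(ln), reference_cells = ref)
}

#' @noRd
.resolve_cells <- function(cells, universe) {
  if (is.logical(cells)) return(universe[cells])
  if (is.numeric(cells)) return(universe[cells])
  .check(all(cells %in% universe), "unknown reference cell id(s)")
  as.character(cells)
}

#' Genomic sliding windows over retained genes
#'
#' Sorts the retained genes by start position within each chromosome and
#' forms every contiguous run of `window_size` genes (stride one gene), so
#' a chromosome with n >= window_size genes yields n - window_size + 1
#' windows. A chromosome with fewer genes than the window collapses to a
#' single window holding all of them; an empty chromosome contributes none.
#'
#' @param gene_anno data.frame with gene_id, chromosome, start_position.
#' @param retained_genes gene ids the relative-expression step kept.
#' @param window_size genes per window (default 100).
#' @return list of windows, each `list(chromosome, genes)` with genes in
#'   genomic order.
#' @export
sliding_windows <- function(gene_anno, retained_genes, window_size = 100) {
  .check(window_size >= 1, "window_size must be at least 1")
  anno <- gene_anno[match(retained_genes, gene_anno$gene_id), , drop = FALSE]
  .check(!anyNA(anno$gene_id), "retained gene absent from annotation")
  windows <- list()
  for (chr in unique(anno$chromosome)) {
    sub <- anno[anno$chromosome == chr, , drop = FALSE]
    sub <- sub[order(sub$start_position), , drop = FALSE]
    n <- nrow(sub)
    if (n == 0) next
    if (n < window_size) {
      windows[[length(windows) + 1]] <- list(chromosome = chr,
                                             genes = sub$gene_id)
    } else {
      for (s in seq_len(n - window_size + 1)) {
        windows[[length(windows) + 1]] <-
          list(chromosome = chr, genes = sub$gene_id[s:(s + window_size - 1)])
      }
    }
  }
  windows
}

#' Windowed CNV profile
#'
#' CNVi(cell, window) is the arithmetic mean of the cell's relative
#' expression over the window's genes.
#'
#' @param relative a `relative_expression()` result (or a gene x cell
#'   matrix with gene rownames).
#' @param windows window list from [sliding_windows()].
#' @return a `cnv_profile`: list with `windows`, `cnv_matrix` (cell x
#'   window), `reference_cells`, and unset `cnv_score` / `is_malignant`.
#' @export
cnv_profile <- function(relative, windows) {
  rel <- if (is.list(relative) && !is.null(relative$rel)) relative$rel
         else relative
  .check(length(windows) > 0, "no windows supplied")
  all_genes <- unique(unlist(lapply(windows, `[[`, "genes")))
  missing <- setdiff(all_genes, rownames(rel))
  .check(length(missing) == 0, "window references dropped gene(s): ",
         paste(utils::head(missing, 3), collapse = ", "))
  idx <- lapply(windows, function(w) match(w$genes, rownames(rel)))
  W <- Matrix::sparseMatrix(
    i = rep(seq_along(idx), lengths(idx)),
    j = unlist(idx),
    x = rep(1 / lengths(idx), lengths(idx)),
    dims = c(length(windows), nrow(rel)))
  cnvi <- as.matrix(Matrix::t(W %*% rel))  # cells x windows
  rownames(cnvi) <- colnames(rel)
  structure(list(windows = windows, cnv_matrix = cnvi,
                 reference_cells = if (is.list(relative))
                   relative$reference_cells else NULL,
                 cnv_score = NULL, is_malignant = NULL,
                 threshold = NULL),
            class = "cnv_profile")
}

#' CNV score and malignancy call
#'
#' The per-cell CNV score is the mean of squared CNVi over all windows;
#' cells whose score lies strictly above `threshold` (default 0.04) are
#' called malignant.
#'
#' @param profile a `cnv_profile`.
#' @param threshold malignancy cut on the score; strict ("above").
#' @return the profile with `cnv_score`, `is_malignant` and `threshold`
#'   filled in.
#' @export
cnv_score_and_call <- function(profile, threshold = 0.04) {
  .check(inherits(profile, "cnv_profile"), "expected a cnv_profile")
  .check(ncol(profile$cnv_matrix) > 0, "profile has zero windows")
  score <- rowMeans(profile$cnv_matrix^2)
  profile$cnv_score <- score
  profile$is_malignant <- score > threshold
  profile$threshold <- threshold
  profile
}

#' One-call malignancy classification
#'
#' Convenience chain of [relative_expression()], [sliding_windows()],
#' [cnv_profile()] and [cnv_score_and_call()].
#'
#' @inheritParams relative_expression
#' @inheritParams sliding_windows
#' @inheritParams cnv_score_and_call
#' @return completed `cnv_profile`.
#' @export
call_malignant <- function(data, reference_cells, window_size = 100,
                           expression_cutoff = 0.1, clip = 3,
                           threshold = 0.04, scale_factor = 1e4) {
  rel <- relative_expression(data, reference_cells,
                             expression_cutoff = expression_cutoff,
                             clip = clip, scale_factor = scale_factor)
  wins <- sliding_windows(.get_gene_anno(data), rel$genes,
                          window_size = window_size)
  cnv_score_and_call(cnv_profile(rel, wins), threshold = threshold)
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile:", nrow(x$cnv_matrix), "cells x", ncol(x$cnv_matrix),
      "windows\n")
  if (!is.null(x$cnv_score)) {
    cat("  malignant:", sum(x$is_malignant), "/", length(x$is_malignant),
        "at threshold", x$threshold, "\n")
  }
  invisible(x)
}
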