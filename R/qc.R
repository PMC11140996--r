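#' Per-cell quality-control metrics and filter calls
#'
#' Computes detected-gene counts and the mitochondrial count fraction for
#' every cell and applies the preprocessing rule: cells with fewer than
#' `min_genes` detected genes or a mitochondrial fraction strictly above
#' `max_mito` fail. Both cuts are strict inequalities, so a cell with
#' exactly `min_genes` genes or exactly `max_mito` mitochondrial content is
#' kept. The mitochondrial fraction is computed on raw counts.
#'
#' @param data SingleCellExperiment whose gene annotation carries an
#'   `is_mitochondrial` flag, or a matrix together with `is_mito`.
#' @param min_genes minimum detected genes (default 250; "fewer than"
#'   excludes).
#' @param max_mito maximal mitochondrial count fraction (default 0.30;
#'   "more than" excludes).
#' @param is_mito logical per-gene vector; only needed for matrix input.
#' @return data.frame, one row per cell: `cell_id`, `n_genes_detected`,
#'   `mito_fraction`, `pass_filters`, `reason` (one of `low_genes`,
#'   `high_mito`, `pass`). Doublet columns are added later by
#'   [consensus_doublet_call()]. A zero-count cell fails as `low_genes`,
#'   with `mito_fraction` 0.
#' @export
compute_cell_qc <- function(data, min_genes = 250, max_mito = 0.30,
                            is_mito = NULL) {
  counts <- .get_counts(data)
  if (is.null(is_mito)) is_mito <- .get_gene_anno(data)$is_mitochondrial
  .check(length(is_mito) == nrow(counts),
         "is_mitochondrial flag length must match gene count")
  total <- Matrix::colSums(counts)
  n_det <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(counts[is_mito, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 0)
  reason <- ifelse(n_det < min_genes, "low_genes",
                   ifelse(mito_frac > max_mito, "high_mito", "pass"))
  data.frame(
    cell_id = if (!is.null(colnames(counts))) colnames(counts)
              else as.character(seq_len(ncol(counts))),
    n_genes_detected = as.integer(n_det),
    mito_fraction = as.numeric(mito_frac),
    pass_filters = reason == "pass",
    reason = reason,
    stringsAsFactors = FALSE)
}

#' Consensus doublet call over several detectors
#'
#' A cell is flagged as a doublet when at least `min_votes` detectors call
#' it, where detector i calls a cell iff its score is at or above
#' `thresholds[i]`. Detectors may supply continuous scores or already
#' thresholded 0/1 calls (with threshold 0.5, say).
#'
#' @param scores list of per-cell numeric score vectors, one per detector
#'   (at least two), all the same length.
#' @param thresholds per-detector score thresholds; a single value is
#'   recycled. Default 0.5.
#' @param min_votes votes needed to flag a cell (default 2, the
#'   "at least two algorithms" rule).
#' @return data.frame with `doublet_votes` (count of calling detectors) and
#'   `is_doublet`.
#' @export
consensus_doublet_call <- function(scores, thresholds = 0.5, min_votes = 2) {
  .check(is.list(scores) && length(scores) >= 2,
         "need score vectors from at least two detectors")
  n <- length(scores[[1]])
  .check(all(vapply(scores, length, 1L) == n),
         "detector score vectors have mismatched lengths")
  thresholds <- rep_len(thresholds, length(scores))
  calls <- mapply(function(s, th) s >= th, scores, thresholds)
  votes <- as.integer(rowSums(matrix(calls, nrow = n)))
  data.frame(doublet_votes = votes, is_doublet = votes >= min_votes)
}
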