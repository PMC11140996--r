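#' Library-size log-normalization
#'
#' Scales each cell's counts to a fixed total, then applies `log(x + 1)`.
#' This is the normalization used throughout the package: CNV profiling,
#' differential expression and gene-set scoring all operate on these values.
#'
#' @param counts gene x cell matrix of non-negative counts (dense or sparse).
#' @param scale_factor fixed library size every cell is scaled to
#'   (default 10000, the droplet-data convention).
#' @return gene x cell matrix of log-normalized expression, same class
#'   family as the input (sparse stays sparse). Cells with zero total
#'   counts are returned as all-zero columns.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  lib <- Matrix::colSums(counts)
  lib[lib == 0] <- 1
  if (inherits(counts, "sparseMatrix")) {
    out <- counts %*% Matrix::Diagonal(ncol(counts), scale_factor / lib)
    out@x <- log1p(out@x)
    dimnames(out) <- dimnames(counts)
    out
  } else {
    log1p(sweep(counts, 2, scale_factor / lib, `*`))
  }
}

#' Extract the counts matrix from a SingleCellExperiment or matrix
#' @noRd
.get_counts <- function(x) {
  if (is(x, "SingleCellExperiment") || is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else if (is.matrix(x) || inherits(x, "Matrix")) {
    x
  } else {
    stop("expected a SingleCellExperiment or a gene x cell matrix")
  }
}

#' Gene annotation table (gene_id, chromosome, start_position,
#' is_mitochondrial) from a SingleCellExperiment
#' @noRd
.get_gene_anno <- function(x) {
  if (!is(x, "SummarizedExperiment")) {
    stop("gene annotation requires a SingleCellExperiment input")
  }
  anno <- as.data.frame(SummarizedExperiment::rowData(x))
  need <- c("gene_id", "chromosome", "start_position", "is_mitochondrial")
  miss <- setdiff(need, colnames(anno))
  if (length(miss) > 0) {
    stop("gene annotation lacks column(s): ", paste(miss, collapse = ", "))
  }
  anno
}

#' @noRd
.get_cell_meta <- function(x) {
  if (!is(x, "SummarizedExperiment")) {
    stop("cell metadata requires a SingleCellExperiment input")
  }
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Stop unless condition holds
#' @noRd
.check <- function(cond, ...) if (!isTRUE(cond)) stop(..., call. = FALSE)
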