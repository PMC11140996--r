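#' Write a dataset as a 10x-style Matrix Market triplet
#'
#' Writes `matrix.mtx` (coordinate integer general), `features.tsv`,
#' `barcodes.tsv`, plus full `gene_anno.tsv` and `cell_meta.tsv` tables.
#' [read_dataset()] inverts this exactly.
#'
#' @param data SingleCellExperiment with a `counts` assay.
#' @param directory output directory (created if absent).
#' @param overwrite allow writing into a directory that already contains a
#'   `matrix.mtx`; default `FALSE` refuses.
#' @return the directory, invisibly.
#' @export
write_dataset <- function(data, directory, overwrite = FALSE) {
  counts <- .get_counts(data)
  if (dir.exists(directory) && file.exists(file.path(directory, "matrix.mtx")) &&
      !overwrite) {
    stop("'", directory, "' already holds a dataset; use overwrite = TRUE")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  .write_mtx_integer(counts, file.path(directory, "matrix.mtx"))

  anno <- .get_gene_anno(data)
  meta <- .get_cell_meta(data)
  writeLines(paste(anno$gene_id, anno$gene_id, "Gene Expression", sep = "\t"),
             file.path(directory, "features.tsv"))
  writeLines(colnames(counts), file.path(directory, "barcodes.tsv"))
  write.table(anno, file.path(directory, "gene_anno.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(meta, file.path(directory, "cell_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(directory)
}

# Matrix::writeMM emits a "real" typed header; counts are integer by
# contract, so the triplet is written directly in integer format.
#' @noRd
.write_mtx_integer <- function(m, path) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  m <- Matrix::drop0(m)
  tm <- methods::as(m, "TsparseMatrix")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(nrow(m), ncol(m), length(tm@x))), con)
  if (length(tm@x) > 0) {
    write.table(data.frame(i = tm@i + 1L, j = tm@j + 1L,
                           x = format(tm@x, scientific = FALSE, trim = TRUE)),
                con, sep = " ", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param directory directory holding matrix.mtx, barcodes.tsv,
#'   gene_anno.tsv and cell_meta.tsv.
#' @return SingleCellExperiment with sparse counts, cell metadata and gene
#'   annotation restored.
#' @export
read_dataset <- function(directory) {
  mtx <- file.path(directory, "matrix.mtx")
  .check(file.exists(mtx), "no matrix.mtx under '", directory, "'")
  counts <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
  barcodes <- readLines(file.path(directory, "barcodes.tsv"))
  anno <- read.delim(file.path(directory, "gene_anno.tsv"),
                     stringsAsFactors = FALSE)
  meta <- read.delim(file.path(directory, "cell_meta.tsv"),
                     stringsAsFactors = FALSE)
  dimnames(counts) <- list(anno$gene_id, barcodes)
  SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(meta, row.names = barcodes),
    rowData = DataFrame(anno, row.names = anno$gene_id))
}

#' Serialize / restore a synthetic design as YAML
#'
#' @param design a `synthetic_design`.
#' @param path file path for the YAML config.
#' @return `write_design` the path invisibly; `read_design` a validated
#'   `synthetic_design` equal to the one written.
#' @export
write_design <- function(design, path) {
  d <- unclass(design)
  d$programs <- lapply(design$programs, unclass)
  d$cnv_segments <- lapply(design$cnv_segments, unclass)
  d$cell_type_props <- lapply(design$cell_type_props, as.list)
  yaml::write_yaml(d, path, precision = 15L)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  d <- yaml::read_yaml(path)
  d$programs <- lapply(d$programs, function(p) {
    gene_program(p$name, unlist(p$genes), unlist(p$active_tissues),
                 p$log2_effect, cell_types = unlist(p$cell_types))
  })
  d$cnv_segments <- lapply(d$cnv_segments, function(s) {
    cnv_segment(s$chromosome, s$start_gene_index, s$end_gene_index,
                s$copy_ratio)
  })
  d$cell_type_props <- lapply(d$cell_type_props, unlist)
  d$tissues <- unlist(d$tissues)
  d$malignant_tissues <- unlist(d$malignant_tissues)
  do.call(synthetic_design, d)
}
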