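#' Graph-based cell clustering (delegating stage)
#'
#' Standard log-normalize / highly-variable-genes / PCA / shared-nearest-
#' neighbor graph / Louvain pipeline producing the cell groupings the
#' bespoke analyses consume. The graph is built by scran and partitioned by
#' igraph; this stage deliberately delegates to those libraries rather than
#' re-implementing them. Deterministic for a fixed seed.
#'
#' @param data SingleCellExperiment or counts matrix (QC-passing cells).
#' @param n_hvg number of most-variable genes (default 1000).
#' @param n_pcs principal components kept (default 15).
#' @param k_neighbors SNN graph neighborhood size (default 20).
#' @param resolution Louvain resolution (default 0.8).
#' @param seed RNG seed.
#' @param scale_factor library size for normalization.
#' @return a `cluster_assignment`: list with `labels` (per-cell factor) and
#'   `params` (the full parameter record).
#' @export
cluster_cells <- function(data, n_hvg = 1000, n_pcs = 15, k_neighbors = 20,
                          resolution = 0.8, seed = 0, scale_factor = 1e4) {
  counts <- .get_counts(data)
  .check(ncol(counts) > n_pcs, "need more cells than principal components")
  set.seed(seed)
  ln <- as.matrix(log_normalize(counts, scale_factor = scale_factor))
  v <- apply(ln, 1, var)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(ln)))]
  emb <- t(ln[hvg, , drop = FALSE])
  if (all(v[hvg] == 0)) {
    labels <- factor(rep("1", ncol(counts)))  # identical cells: one cluster
  } else {
    rank <- min(n_pcs, ncol(emb) - 1, nrow(emb) - 1)
    pcs <- prcomp(emb, center = TRUE, scale. = FALSE, rank. = rank)$x
    g <- scran::buildSNNGraph(pcs, k = k_neighbors, transposed = TRUE)
    comm <- igraph::cluster_louvain(g, resolution = resolution)
    labels <- factor(igraph::membership(comm))
  }
  names(labels) <- colnames(counts)
  structure(list(labels = labels,
                 params = list(n_hvg = n_hvg, n_pcs = n_pcs,
                               k_neighbors = k_neighbors,
                               resolution = resolution, seed = seed,
                               scale_factor = scale_factor)),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("cluster_assignment:", length(x$labels), "cells in",
      nlevels(x$labels), "clusters (resolution",
      x$params$resolution, ", seed", x$params$seed, ")\n")
  invisible(x)
}
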