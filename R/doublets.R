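#' Simulation-based kNN doublet score
#'
#' Scores every cell by the fraction of its k nearest neighbors — in PCA
#' space of log-normalized expression, observed cells and simulated
#' doublets pooled — that are simulated doublets. Simulated doublets are
#' built exactly like the generator's planted ones: two random cells from
#' the same sample summed and downscaled to the sample's mean library size
#' (see [make_doublet()]). Distance ties at the k-th neighbor are averaged
#' over, so the score is invariant to point ordering.
#'
#' @param data SingleCellExperiment or counts matrix.
#' @param n_simulated number of simulated doublets to pool in (default:
#'   `ceiling(n_cells / 3)`, making simulated points a quarter of the pool
#'   as in common practice; a cell in a homogeneous region then sees well
#'   under half simulated neighbors, while cells in the heterotypic-doublet
#'   region see mostly simulated ones).
#' @param k_neighbors neighborhood size (default 20); must be smaller than
#'   the number of cells.
#' @param n_pcs,n_hvg PCA dimensions and number of most-variable genes the
#'   embedding uses.
#' @param sample_ids per-cell sample labels restricting doublet parents to
#'   one sample; taken from `colData(data)$sample_id` when present,
#'   otherwise all cells form one sample.
#' @param seed RNG seed for pair sampling and downsampling.
#' @return numeric per-cell score in [0, 1].
#' @export
score_doublets_simulated <- function(data, n_simulated = NULL,
                                     k_neighbors = 20, n_pcs = 10,
                                     n_hvg = 1000, sample_ids = NULL,
                                     seed = 0) {
  counts <- .get_counts(data)
  n_cells <- ncol(counts)
  .check(k_neighbors < n_cells, "k_neighbors must be below the cell count")
  .check(n_cells >= 2 * k_neighbors,
         "need at least 2 * k_neighbors cells")
  if (is.null(n_simulated)) n_simulated <- ceiling(n_cells / 3)
  if (is.null(sample_ids) && is(data, "SummarizedExperiment")) {
    cd <- .get_cell_meta(data)
    if ("sample_id" %in% colnames(cd)) sample_ids <- cd$sample_id
  }
  if (is.null(sample_ids)) sample_ids <- rep("all", n_cells)

  set.seed(seed)
  lib <- Matrix::colSums(counts)
  target <- vapply(split(lib, sample_ids), mean, 0)
  parent1 <- sample(n_cells, n_simulated, replace = TRUE)
  parent2 <- vapply(parent1, function(i) {
    peers <- which(sample_ids == sample_ids[i])
    peers <- peers[peers != i]
    if (length(peers) == 0) i else peers[sample.int(length(peers), 1)]
  }, 1L)
  sim <- vapply(seq_len(n_simulated), function(s) {
    make_doublet(counts[, parent1[s]], counts[, parent2[s]],
                 round(target[[sample_ids[parent1[s]]]]))
  }, numeric(nrow(counts)))

  pooled <- cbind(as.matrix(counts), sim)
  ln <- as.matrix(log_normalize(pooled))
  v <- apply(ln, 1, var)
  hvg <- order(v, decreasing = TRUE)[seq_len(min(n_hvg, nrow(ln)))]
  emb <- ln[hvg, , drop = FALSE]
  if (all(v[hvg] == 0)) {
    pcs <- matrix(0, ncol(pooled), n_pcs)  # degenerate: all points coincide
  } else {
    pcs <- prcomp(t(emb), center = TRUE, scale. = FALSE,
                  rank. = min(n_pcs, nrow(emb), ncol(pooled)))$x
  }

  is_sim <- c(rep(FALSE, n_cells), rep(TRUE, n_simulated))
  self_norm <- rowSums(pcs^2)
  scores <- numeric(n_cells)
  block <- 512L
  for (start in seq(1, n_cells, by = block)) {
    idx <- start:min(start + block - 1L, n_cells)
    d2 <- outer(self_norm[idx], rep(1, nrow(pcs))) +
      outer(rep(1, length(idx)), self_norm) -
      2 * pcs[idx, , drop = FALSE] %*% t(pcs)
    for (r in seq_along(idx)) {
      v2 <- d2[r, ]
      v2[idx[r]] <- Inf  # never a neighbor of itself
      thr <- sort(v2, partial = k_neighbors)[k_neighbors]
      closer <- v2 < thr - 1e-9
      tied <- abs(v2 - thr) <= 1e-9
      n_closer <- sum(closer)
      sim_close <- sum(is_sim[closer])
      # average over tie-breaks at the k-th neighbor distance
      sim_tied_frac <- if (any(tied)) mean(is_sim[tied]) else 0
      scores[idx[r]] <- (sim_close +
                           (k_neighbors - n_closer) * sim_tied_frac) /
        k_neighbors
    }
  }
  scores
}
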