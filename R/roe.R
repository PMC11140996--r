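#' Tissue preference by ratio of observed to expected cell numbers (Ro/e)
#'
#' Cross-tabulates cluster by tissue and divides observed counts by the
#' expected counts of the chi-square independence model,
#' `expected_ij = row_i * col_j / N`. Ro/e above 1 marks a cluster enriched
#' in a tissue relative to a tissue-agnostic distribution of that cluster.
#'
#' @param cluster_labels,tissue_labels per-cell label vectors of equal
#'   length.
#' @return a `roe_matrix`: list with `roe` (clusters x tissues), `observed`
#'   (integer table) and `expected`. Clusters with zero cells are dropped.
#' @export
roe <- function(cluster_labels, tissue_labels) {
  .check(length(cluster_labels) == length(tissue_labels),
         "label vectors must have equal length")
  .check(length(cluster_labels) > 0, "empty input")
  obs <- table(cluster = as.character(cluster_labels),
               tissue = as.character(tissue_labels))
  obs <- obs[rowSums(obs) > 0, , drop = FALSE]
  .check(all(colSums(obs) > 0), "every tissue needs at least one cell")
  expected <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  structure(list(roe = unclass(obs) / expected,
                 observed = unclass(obs), expected = expected),
            class = "roe_matrix")
}

#' @export
print.roe_matrix <- function(x, digits = 3, ...) {
  cat("Ro/e (", nrow(x$roe), "clusters x", ncol(x$roe), "tissues )\n")
  print(round(x$roe, digits))
  invisible(x)
}

#' Tidy Ro/e table
#'
#' @param x a `roe_matrix`.
#' @param digits decimals for the reported ratio (default 3).
#' @return data.frame with cluster, tissue, observed, expected, roe.
#' @export
roe_table <- function(x, digits = 3) {
  .check(inherits(x, "roe_matrix"), "expected a roe_matrix")
  data.frame(
    cluster = rep(rownames(x$roe), ncol(x$roe)),
    tissue = rep(colnames(x$roe), each = nrow(x$roe)),
    observed = as.vector(x$observed),
    expected = as.vector(x$expected),
    roe = round(as.vector(x$roe), digits),
    stringsAsFactors = FALSE)
}
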