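#' Bimodal likelihood-ratio test for single-cell expression
#'
#' Models log-normalized expression in each group as a mixture of a point
#' mass at zero (dropout) and a normal component on the positive values.
#' The statistic is the likelihood ratio of fitting the two groups jointly
#' versus separately: `2 * (llik_A + llik_B - llik_pooled)`, referred to a
#' chi-square with 3 degrees of freedom (mixing weight, mean and variance
#' re-estimated per group).
#'
#' The mixing weight is clamped to `[1e-5, 1 - 1e-5]` and the normal
#' component's variance floored at `var_floor`, so groups with all-zero or
#' all-identical values are handled rather than degenerate.
#'
#' @param x,y numeric log-expression vectors for groups A and B, each with
#'   at least 2 cells.
#' @param var_floor lower bound on the positive component's variance
#'   (default 1e-6).
#' @return list with `lrt_stat` (non-negative up to numerical tolerance)
#'   and `p_value` (upper chi-square tail, df = 3).
#' @export
bimod_lrt <- function(x, y, var_floor = 1e-6) {
  .check(length(x) >= 2 && length(y) >= 2, "both groups need >= 2 cells")
  ll <- function(v) .bimod_loglik(v, var_floor)
  stat <- 2 * (ll(x) + ll(y) - ll(c(x, y)))
  stat <- max(stat, 0)
  list(lrt_stat = stat, p_value = pchisq(stat, df = 3, lower.tail = FALSE))
}

# log-likelihood of the zero/normal mixture at its MLE
#' @noRd
.bimod_loglik <- function(v, var_floor = 1e-6) {
  pos <- v[v > 0]
  n <- length(v)
  alpha <- min(max(length(pos) / n, 1e-5), 1 - 1e-5)
  lik <- (n - length(pos)) * log(1 - alpha)
  if (length(pos) > 0) {
    m <- mean(pos)
    s <- sqrt(max(mean((pos - m)^2), var_floor))  # ML variance, floored
    lik <- lik + length(pos) * log(alpha) +
      sum(dnorm(pos, m, s, log = TRUE))
  }
  lik
}

#' Two-group differential expression
#'
#' Tests every gene between two groups of cells on log-normalized
#' expression, with the bimodal LRT (default) or a Wilcoxon rank-sum test.
#' The fold change is the ratio of the groups' mean de-logged expression,
#' `(mean(expm1(logexpr_A)) + eps) / (mean(expm1(logexpr_B)) + eps)`. A
#' gene is significant iff fold change exceeds `fc_threshold` *and* raw p
#' falls below `p_threshold` (no multiple-testing correction enters the
#' call; a BH-adjusted column is reported alongside).
#'
#' @param data SingleCellExperiment or gene x cell counts matrix.
#' @param group_labels per-cell group labels.
#' @param contrast length-2 character vector `c(A, B)`; positive fold
#'   change means higher in A.
#' @param fc_threshold fold-change gate (default 1.2, strict).
#' @param p_threshold p-value gate (default 0.001, strict).
#' @param test "bimod" or "wilcoxon".
#' @param min_cells minimum cells per group (default 3).
#' @param scale_factor library size for normalization.
#' @return data.frame sorted by descending fold change then ascending p:
#'   gene_id, log2_fc, fold_change, pct_a, pct_b, lrt_stat (NA for
#'   wilcoxon), p_value, p_adj, significant.
#' @export
find_degs <- function(data, group_labels, contrast, fc_threshold = 1.2,
                      p_threshold = 0.001, test = c("bimod", "wilcoxon"),
                      min_cells = 3, scale_factor = 1e4) {
  test <- match.arg(test)
  counts <- .get_counts(data)
  .check(length(group_labels) == ncol(counts),
         "group_labels length must match cell count")
  .check(length(contrast) == 2, "contrast must name two groups")
  ia <- which(group_labels == contrast[1])
  ib <- which(group_labels == contrast[2])
  .check(length(ia) >= min_cells && length(ib) >= min_cells,
         "need at least ", min_cells, " cells in each contrast group")

  ln <- as.matrix(log_normalize(counts[, c(ia, ib), drop = FALSE],
                                scale_factor = scale_factor))
  a <- seq_along(ia)
  b <- length(ia) + seq_along(ib)
  eps <- 1e-9
  mean_a <- rowMeans(expm1(ln[, a, drop = FALSE]))
  mean_b <- rowMeans(expm1(ln[, b, drop = FALSE]))
  fc <- (mean_a + eps) / (mean_b + eps)
  pct_a <- rowMeans(ln[, a, drop = FALSE] > 0)
  pct_b <- rowMeans(ln[, b, drop = FALSE] > 0)

  n_genes <- nrow(ln)
  stat <- rep(NA_real_, n_genes)
  pval <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    if (test == "bimod") {
      r <- bimod_lrt(ln[g, a], ln[g, b])
      stat[g] <- r$lrt_stat
      pval[g] <- r$p_value
    } else {
      pval[g] <- suppressWarnings(
        wilcox.test(ln[g, a], ln[g, b], exact = FALSE)$p.value)
      if (is.na(pval[g])) pval[g] <- 1  # constant gene: no evidence
    }
  }
  out <- data.frame(
    gene_id = if (!is.null(rownames(ln))) rownames(ln)
              else as.character(seq_len(n_genes)),
    log2_fc = log2(fc), fold_change = fc,
    pct_a = pct_a, pct_b = pct_b,
    lrt_stat = stat, p_value = pval,
    p_adj = p.adjust(pval, "BH"),
    stringsAsFactors = FALSE)
  out$significant <- out$fold_change > fc_threshold & out$p_value < p_threshold
  out[order(-out$fold_change, out$p_value), , drop = FALSE]
}
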