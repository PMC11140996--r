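#' Generate a synthetic multi-tissue dataset
#'
#' Draws a gene x cell count matrix from a [synthetic_design()]. Counts are
#' negative binomial around per-gene log-normal baseline means; planted
#' program genes have their means multiplied by `2^log2_effect` in active
#' tissues (and matching cell types); malignant epithelial cells carry the
#' design's copy-number segments as mean multipliers; damaged cells have
#' mitochondrial means inflated to the design's target fraction; doublets
#' are sums of two random same-sample singlets downscaled to the sample's
#' mean singlet library size. All randomness flows from `design$seed`, so
#' the same design yields bit-identical data.
#'
#' @param design a validated `synthetic_design`.
#' @return a [SingleCellExperiment::SingleCellExperiment] with a sparse
#'   `counts` assay, per-cell metadata (`cell_id`, `patient`, `tissue`,
#'   `sample_id`, `true_cell_type`, `true_is_malignant`, `true_is_doublet`,
#'   `true_is_mito_high`) and gene annotation (`gene_id`, `chromosome`,
#'   `start_position`, `is_mitochondrial`).
#' @export
generate_dataset <- function(design) {
  validate_design(design)
  set.seed(design$seed)
  anno <- design_gene_anno(design)
  n_genes <- design$n_genes
  mito_idx <- which(anno$is_mitochondrial)
  mu0 <- rlnorm(n_genes, design$baseline_log_mean, design$baseline_log_sd)
  nb_size <- 1 / design$nb_dispersion

  # genomic index of each segment's genes (contiguous run on one chromosome)
  seg_genes <- lapply(design$cnv_segments, function(seg) {
    on_chr <- which(anno$chromosome == seg$chromosome)
    on_chr <- on_chr[order(anno$start_position[on_chr])]
    on_chr[seg$start_gene_index:seg$end_gene_index]
  })

  # -- cell sheet ------------------------------------------------------------
  meta <- list()
  for (p in seq_len(design$n_patients)) {
    for (tt in design$tissues) {
      props <- design$cell_type_props[[tt]]
      n <- design$cells_per_sample
      n_per <- floor(props * n)
      rem <- n - sum(n_per)
      if (rem > 0) {  # largest-remainder rounding
        extra <- order(props * n - n_per, decreasing = TRUE)[seq_len(rem)]
        n_per[extra] <- n_per[extra] + 1
      }
      types <- rep(names(props), n_per)
      malignant <- rep(FALSE, n)
      if (tt %in% design$malignant_tissues && length(design$cnv_segments) > 0) {
        epi <- which(types == "epithelial")
        n_mal <- round(design$malignant_fraction * length(epi))
        if (n_mal > 0) malignant[sample(epi, n_mal)] <- TRUE
      }
      meta[[length(meta) + 1]] <- data.frame(
        patient = paste0("P", p), tissue = tt,
        sample_id = paste0("P", p, "_", tt),
        true_cell_type = types, true_is_malignant = malignant,
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, meta)
  n_sing <- nrow(meta)
  meta$true_is_doublet <- FALSE
  meta$true_is_mito_high <- FALSE
  n_high <- round(design$mito_high_fraction * n_sing)
  if (n_high > 0) meta$true_is_mito_high[sample(n_sing, n_high)] <- TRUE
  meta$cell_id <- paste0(meta$sample_id, "_C",
                         stats::ave(seq_len(n_sing), meta$sample_id,
                                    FUN = seq_along))

  # -- expected means per condition class ------------------------------------
  mean_for <- local({
    cache <- new.env(parent = emptyenv())
    function(tissue, type, malignant, mito_high) {
      key <- paste(tissue, type, malignant, mito_high, sep = "|")
      if (!is.null(cache[[key]])) return(cache[[key]])
      mu <- mu0
      for (pr in design$programs) {
        if (tissue %in% pr$active_tissues &&
            (is.null(pr$cell_types) || type %in% pr$cell_types)) {
          mu[match(pr$genes, anno$gene_id)] <-
            mu[match(pr$genes, anno$gene_id)] * 2^pr$log2_effect
        }
      }
      if (malignant) {
        for (k in seq_along(seg_genes)) {
          mu[seg_genes[[k]]] <- mu[seg_genes[[k]]] *
            design$cnv_segments[[k]]$copy_ratio
        }
      }
      if (mito_high && length(mito_idx) > 0) {
        m <- sum(mu[mito_idx]); r <- sum(mu[-mito_idx])
        tgt <- design$mito_high_target
        mu[mito_idx] <- mu[mito_idx] * tgt * r / ((1 - tgt) * m)
      }
      cache[[key]] <- mu
      mu
    }
  })

  counts <- matrix(0L, n_genes, n_sing)
  for (j in seq_len(n_sing)) {
    mu <- mean_for(meta$tissue[j], meta$true_cell_type[j],
                   meta$true_is_malignant[j], meta$true_is_mito_high[j])
    counts[, j] <- rnbinom(n_genes, size = nb_size, mu = mu)
  }

  # -- doublets --------------------------------------------------------------
  n_doub_per <- round(design$doublet_rate * design$cells_per_sample)
  if (n_doub_per > 0) {
    dcols <- list(); dmeta <- list()
    for (sid in unique(meta$sample_id)) {
      cells <- which(meta$sample_id == sid)
      if (length(cells) < 2) next
      target <- round(mean(colSums(counts[, cells, drop = FALSE])))
      for (d in seq_len(n_doub_per)) {
        pair <- sample(cells, 2)
        dbl <- make_doublet(counts[, pair[1]], counts[, pair[2]], target)
        dcols[[length(dcols) + 1]] <- dbl
        dmeta[[length(dmeta) + 1]] <- data.frame(
          patient = meta$patient[cells[1]], tissue = meta$tissue[cells[1]],
          sample_id = sid,
          true_cell_type = paste(sort(meta$true_cell_type[pair]),
                                 collapse = "+"),
          true_is_malignant = any(meta$true_is_malignant[pair]),
          true_is_doublet = TRUE, true_is_mito_high = FALSE,
          cell_id = paste0(sid, "_D", d), stringsAsFactors = FALSE)
      }
    }
    counts <- cbind(counts, do.call(cbind, dcols))
    meta <- rbind(meta, do.call(rbind, dmeta))
  }

  counts <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(counts) <- list(anno$gene_id, meta$cell_id)
  SingleCellExperiment(
    assays = list(counts = counts),
    colData = DataFrame(meta[, c("cell_id", "patient", "tissue", "sample_id",
                                 "true_cell_type", "true_is_malignant",
                                 "true_is_doublet", "true_is_mito_high")],
                        row.names = meta$cell_id),
    rowData = DataFrame(anno, row.names = anno$gene_id))
}

#' Combine two cells into a doublet column
#'
#' Sums the two count vectors and, when the sum exceeds `target_size`,
#' multinomially downsamples it to `target_size` total counts — the same
#' construction doublet-detection tools use for their simulated doublets.
#'
#' @param x,y integer count vectors of equal length.
#' @param target_size library size to downsample to (typically the mean
#'   singlet library size of the cells' sample).
#' @return integer count vector.
#' @export
make_doublet <- function(x, y, target_size) {
  s <- x + y
  tot <- sum(s)
  if (tot > target_size && tot > 0) {
    s <- as.integer(rmultinom(1, target_size, s / tot))
  }
  s
}
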