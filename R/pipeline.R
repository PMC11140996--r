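#' Default demo pipeline configuration
#'
#' All stage parameters at the standard preprocessing/analysis defaults:
#' minimum 250 detected genes, maximum 30% mitochondrial counts, doublet
#' consensus at 2 votes, 100-gene CNV windows at expression cutoff 0.1 and
#' malignancy threshold 0.04, DEG gates fold change 1.2 and p 0.001, and
#' 21-gene context score sets. Every stage's randomness derives from the
#' one global `seed` through fixed per-stage offsets.
#'
#' @param seed global pipeline seed.
#' @return nested named list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    version = 1L,
    seed = as.integer(seed),
    design = NULL,  # NULL = default_design(seed)
    qc = list(min_genes = 250, max_mito = 0.30,
              doublet = list(n_detectors = 3L,
                             k_neighbors = c(15L, 20L, 25L),
                             n_pcs = 10L, n_hvg = 1000L,
                             threshold = 0.5, min_votes = 2L)),
    cluster = list(n_hvg = 1000L, n_pcs = 15L, k_neighbors = 20L,
                   resolution = 0.8),
    cnv = list(window_size = 100L, expression_cutoff = 0.1, clip = 3,
               threshold = 0.04, reference_tissues = "peritumor"),
    deg = list(fc_threshold = 1.2, p_threshold = 0.001, test = "bimod"),
    scores = list(top_n = 21L))
}

#' @noRd
.validate_config <- function(config, defaults = default_pipeline_config()) {
  unknown <- setdiff(names(config), names(defaults))
  .check(length(unknown) == 0,
         "unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        nm != "design") {
      .check(is.list(config[[nm]]), "config block '", nm, "' must be a list")
      .validate_config(config[[nm]], defaults[[nm]])
    }
  }
  invisible(config)
}

#' Run the full demo workflow
#'
#' simulate -> qc (filters + doublet consensus) -> cluster -> cnv ->
#' deg/context scores -> Ro/e, writing every stage's tables plus a summary
#' `report.md` under `out_dir`. The demo runs on synthetic data with known
#' truth, so the report can include a malignancy confusion matrix and the
#' planted-program recovery of the context sets. A stage failure aborts
#' with the stage named; tables already written are retained. Identical
#' config and seed reproduce bit-identical outputs.
#'
#' The malignancy stage follows the usual practice of restricting CNV
#' inference to annotated epithelial cells with normal epithelial cells as
#' reference: here the simulator's cell-type labels stand in for the
#' annotation step, and reference cells are the epithelial cells of the
#' configured non-tumor tissues. The doublet consensus runs the package's
#' simulation-based scorer as three independently seeded detector
#' instances and removes cells called by at least `min_votes` of them.
#'
#' @param config configuration list, see [default_pipeline_config()];
#'   unknown keys are rejected. `config$design` may hold a
#'   `synthetic_design` or a YAML path; `NULL` uses [default_design()] at
#'   the global seed.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing output directory.
#' @param verbose print stage progress.
#' @return invisibly, a list with the per-stage objects and `out_dir`.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, overwrite = FALSE, verbose = TRUE) {
  .validate_config(config)
  if (dir.exists(out_dir) && file.exists(file.path(out_dir, "report.md")) &&
      !overwrite) {
    stop("'", out_dir, "' already holds a report; use overwrite = TRUE")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message("[ctxneu] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  seed <- config$seed
  tsv <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)

  ## -- simulate --------------------------------------------------------------
  say("simulate")
  data <- stage("simulate", {
    design <- config$design
    if (is.null(design)) design <- default_design(seed = seed)
    if (is.character(design)) design <- read_design(design)
    write_design(design, file.path(out_dir, "design.yaml"))
    d <- generate_dataset(design)
    write_dataset(d, file.path(out_dir, "data"), overwrite = overwrite)
    d
  })
  meta <- .get_cell_meta(data)

  ## -- qc --------------------------------------------------------------------
  say("qc + doublet consensus")
  qc <- stage("qc", {
    rep <- compute_cell_qc(data, min_genes = config$qc$min_genes,
                           max_mito = config$qc$max_mito)
    db <- config$qc$doublet
    ks <- rep_len(db$k_neighbors, db$n_detectors)
    sc <- lapply(seq_len(db$n_detectors), function(i) {
      score_doublets_simulated(data, k_neighbors = ks[i],
                               n_pcs = db$n_pcs, n_hvg = db$n_hvg,
                               seed = seed + 100L + i)
    })
    cons <- consensus_doublet_call(sc, thresholds = db$threshold,
                                   min_votes = db$min_votes)
    rep$doublet_votes <- cons$doublet_votes
    rep$is_doublet <- cons$is_doublet
    rep$reason[rep$reason == "pass" & rep$is_doublet] <- "doublet"
    rep$pass_filters <- rep$reason == "pass"
    tsv(rep, "qc_report.tsv")
    rep
  })
  kept <- data[, qc$pass_filters]
  kmeta <- .get_cell_meta(kept)

  ## -- cluster ---------------------------------------------------------------
  say("cluster")
  cl <- stage("cluster", {
    a <- cluster_cells(kept, n_hvg = config$cluster$n_hvg,
                       n_pcs = config$cluster$n_pcs,
                       k_neighbors = config$cluster$k_neighbors,
                       resolution = config$cluster$resolution,
                       seed = seed + 201L)
    tsv(data.frame(cell_id = names(a$labels),
                   cluster = as.character(a$labels)), "clusters.tsv")
    a
  })

  ## -- cnv -------------------------------------------------------------------
  say("cnv malignancy")
  cnv <- stage("cnv", {
    epi <- kmeta$true_cell_type == "epithelial"
    .check(any(epi), "no epithelial cells survive QC")
    sub <- kept[, epi]
    smeta <- .get_cell_meta(sub)
    ref <- smeta$cell_id[smeta$tissue %in% config$cnv$reference_tissues]
    prof <- call_malignant(sub, ref,
                           window_size = config$cnv$window_size,
                           expression_cutoff = config$cnv$expression_cutoff,
                           clip = config$cnv$clip,
                           threshold = config$cnv$threshold)
    out <- data.frame(cell_id = smeta$cell_id, tissue = smeta$tissue,
                      cnv_score = as.numeric(prof$cnv_score),
                      is_malignant = prof$is_malignant,
                      true_is_malignant = smeta$true_is_malignant)
    tsv(out, "cnv.tsv")
    list(profile = prof, calls = out)
  })

  ## -- deg + context scores --------------------------------------------------
  say("context scores")
  ctx <- stage("scores", {
    neu <- kept[, kmeta$true_cell_type == "neutrophil"]
    cs <- build_context_scores(neu, top_n = config$scores$top_n,
                               fc_threshold = config$deg$fc_threshold,
                               p_threshold = config$deg$p_threshold,
                               test = config$deg$test)
    for (nm in names(cs$provenance)) {
      tsv(cs$provenance[[nm]], paste0("degs_", nm, ".tsv"))
    }
    set_tab <- data.frame(
      score = rep(names(cs$sets), lengths(cs$sets)),
      gene_id = unlist(cs$sets, use.names = FALSE))
    tsv(set_tab, "context_sets.tsv")
    tsv(cs$scores, "context_scores.tsv")
    cs
  })

  ## -- roe -------------------------------------------------------------------
  say("tissue preference")
  ro <- stage("roe", {
    r <- roe(cl$labels, kmeta$tissue)
    tsv(roe_table(r), "roe.tsv")
    r
  })

  ## -- report ----------------------------------------------------------------
  stage("report", {
    .write_report(out_dir, meta, qc, cnv, ctx, ro, config)
  })
  say("done: ", out_dir)
  invisible(list(data = data, qc = qc, clusters = cl, cnv = cnv,
                 context = ctx, roe = ro, out_dir = out_dir))
}

#' @noRd
.write_report <- function(out_dir, meta, qc, cnv, ctx, ro, config) {
  l <- character(0)
  add <- function(...) l <<- c(l, paste0(...))
  add("# Pipeline report")
  add("")
  add("## QC funnel")
  tab <- table(qc$reason)
  add("| stage | cells |", "\n|---|---|")
  add("| input | ", nrow(qc), " |")
  for (r in c("low_genes", "high_mito", "doublet")) {
    add("| removed: ", r, " | ", if (r %in% names(tab)) tab[[r]] else 0, " |")
  }
  add("| pass | ", sum(qc$pass_filters), " |")
  add("")
  add("## Malignancy calls vs planted truth (epithelial cells)")
  cm <- table(called = cnv$calls$is_malignant,
              truth = cnv$calls$true_is_malignant)
  add("| | truth FALSE | truth TRUE |", "\n|---|---|---|")
  for (cc in rownames(cm)) {
    add("| called ", cc, " | ", paste(cm[cc, ], collapse = " | "), " |")
  }
  add("")
  add("## Context gene sets")
  for (nm in names(ctx$sets)) {
    add("- ", nm, ": ", length(ctx$sets[[nm]]), " genes")
  }
  add("")
  add("## Mean context scores by tissue")
  sc <- ctx$scores
  add("| tissue | nontumor_activating | tissue_residing | tumor_modifying |",
      "\n|---|---|---|---|")
  for (tt in unique(sc$tissue)) {
    m <- sc[sc$tissue == tt, ]
    add("| ", tt, " | ",
        round(mean(m$nontumor_activating), 4), " | ",
        round(mean(m$tissue_residing), 4), " | ",
        round(mean(m$tumor_modifying), 4), " |")
  }
  add("")
  add("## Ro/e (clusters x tissues)")
  rt <- ro$roe
  add("| cluster | ", paste(colnames(rt), collapse = " | "), " |")
  add("|", paste(rep("---|", ncol(rt) + 1), collapse = ""))
  for (cc in rownames(rt)) {
    add("| ", cc, " | ", paste(round(rt[cc, ], 3), collapse = " | "), " |")
  }
  writeLines(l, file.path(out_dir, "report.md"))
  invisible(NULL)
}
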