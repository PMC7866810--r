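#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with a
#' `counts` path or a `synthetic` block, an `outdir`, a global `seed`, and
#' optional stage blocks `preprocess`, `cluster`, `pseudotime`, `de`,
#' `biomarkers` mirroring the corresponding function parameters. Every
#' referenced path must exist at validation time; every stage block has
#' defaults.
#'
#' @param config named list or path to a YAML file.
#' @return the completed configuration list (class `PipelineConfig`).
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("config requires an outdir")
  if (is.null(config$counts) && is.null(config$synthetic))
    stop("config requires a counts path or a synthetic block")
  for (p in c(config$counts, config$preprocess$gene_list,
              config$biomarkers$edges, config$biomarkers$gmt)) {
    if (!is.null(p) && !file.exists(p)) stop("path does not exist: ", p)
  }
  defaults <- list(
    seed = 1L, spikein_prefix = "ERCC-",
    preprocess = list(norm = "scale_to_median_total", minexpr = 0,
                      minnumber = 1, min_cell_counts = 0, mode = NULL,
                      ercc_filter = FALSE, alpha = 0.01,
                      min_biol_disp = 0.25, gene_list = NULL),
    cluster = list(method = "kmeans", k_min = 1, k_max = 8,
                   distance = "pearson", bootstrap = 20, gap_refs = 30,
                   probthr = 1e-3, outminc = 2, embedding = "pca"),
    pseudotime = list(enabled = TRUE),
    de = list(mode = "samseq", cluster_a = NULL, cluster_b = NULL,
              fdr = 0.05, fc = 1, n_resamples = 20, n_permutations = 100),
    biomarkers = list(edges = NULL, min_weight = 0.4, gmt = NULL,
                      inducer = "cart", folds = 10, cp = 0.01,
                      minsplit = 20, max_features = 50))
  for (blk in names(defaults)) {
    if (is.list(defaults[[blk]])) {
      config[[blk]] <- utils::modifyList(defaults[[blk]],
                                         config[[blk]] %||% list())
    } else if (is.null(config[[blk]])) {
      config[[blk]] <- defaults[[blk]]
    }
  }
  structure(config, class = c("PipelineConfig", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(name, outdir, resume, fun) {
  state <- file.path(outdir, "state", paste0(name, ".rds"))
  if (resume && file.exists(state)) return(readRDS(state))
  res <- tryCatch(fun(), error = function(e) {
    writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
         call. = FALSE)
  })
  saveRDS(res, state)
  res
}

#' Run the full biomarker-discovery pipeline
#'
#' Executes preprocess (normalization + filters), clustering (with
#' stability, outlier detection and a 2-D embedding), pseudotemporal
#' ordering, differential expression, and biomarker identification
#' (decision tree with cross-validation, plus network hubs and gene-set
#' enrichment when an edge list / GMT is configured), writing every stage's
#' result tables as TSV under `outdir` together with a JSON run manifest
#' (package version, seeds, parameters, input checksums). Stages are
#' resumable from their last completed output via `resume = TRUE`.
#'
#' All randomness flows from the single global `seed` through fixed
#' per-stage offsets, so a rerun with an identical configuration reproduces
#' every result table byte for byte.
#'
#' @param config configuration list or YAML path, see [pipeline_config()].
#' @param resume reuse completed stage states found under `outdir/state`.
#' @return invisibly, a list with the per-stage result objects and the
#'   manifest.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  cfg <- pipeline_config(config)
  outdir <- cfg$outdir
  dir.create(file.path(outdir, "state"), recursive = TRUE,
             showWarnings = FALSE)
  unlink(file.path(outdir, "FAILED"))
  seed <- as.integer(cfg$seed)

  ## ---- input ----
  input <- .stage("input", outdir, resume, function() {
    if (!is.null(cfg$counts)) {
      read_counts(cfg$counts, spikein_prefix = cfg$spikein_prefix)
    } else {
      sp <- do.call(synthetic_spec,
                    utils::modifyList(cfg$synthetic, list(seed = seed)))
      ds <- simulate_cells(sp)
      write_counts(ds$table, file.path(outdir, "counts.csv"))
      ds$table
    }
  })

  ## ---- preprocess ----
  pp <- cfg$preprocess
  filtered <- .stage("preprocess", outdir, resume, function() {
    norm <- compute_size_factors(input, method = pp$norm)
    tab <- filter_by_expression(norm, minexpr = pp$minexpr,
                                minnumber = pp$minnumber,
                                min_cell_counts = pp$min_cell_counts,
                                mode = pp$mode)
    if (isTRUE(pp$ercc_filter)) {
      fit <- fit_technical_noise(norm, alpha = pp$alpha,
                                 min_biol_disp = pp$min_biol_disp)
      write_tsv(data.frame(gene = names(fit$p_values),
                           p_value = fit$p_values, keep = fit$keep),
                file.path(outdir, "noise_fit.tsv"))
      tab <- filter_by_noise(tab, fit)
    }
    if (!is.null(pp$gene_list))
      tab <- filter_by_gene_list(tab, readLines(pp$gene_list))
    write_tsv(data.frame(gene = tab$gene_ids),
              file.path(outdir, "kept_genes.txt"))
    nm <- attr(tab, "normalized")
    write_tsv(data.frame(gene = rownames(nm), nm, check.names = FALSE),
              file.path(outdir, "normalized.tsv"))
    tab
  })

  ## ---- clustering ----
  cl <- cfg$cluster
  clustered <- .stage("cluster", outdir, resume, function() {
    res <- if (cl$method == "kmeans") {
      cluster_kmeans_gap(filtered, k_range = cl$k_min:cl$k_max,
                         distance = cl$distance, gap_refs = cl$gap_refs,
                         seed = seed + 100L)
    } else {
      cluster_model_based(filtered, k_range = max(1, cl$k_min):cl$k_max,
                          seed = seed + 100L)
    }
    write_tsv(data.frame(cell = names(res$labels), cluster = res$labels),
              file.path(outdir, "labels.tsv"))
    write_tsv(if (res$method == "kmeans") res$gap_curve else res$bic_curve,
              file.path(outdir, "gap_or_bic.tsv"))
    stab <- if (res$k > 1)
      jaccard_stability(filtered, res, n_bootstrap = cl$bootstrap,
                        seed = seed + 100L)
    dmat <- distance_matrix(filtered, "pearson")
    sil <- if (res$k > 1) silhouette_widths(dmat, res$labels)
    if (!is.null(stab))
      write_tsv(data.frame(cluster = seq_len(res$k),
                           jaccard = stab$jaccard,
                           silhouette = as.numeric(sil$cluster_mean_sil)),
                file.path(outdir, "stability.tsv"))
    out <- detect_outliers(filtered, res$labels, probthr = cl$probthr,
                           outminc = cl$outminc)
    write_tsv(data.frame(cell = names(out$outlier),
                         n_outlier_genes = out$n_outlier_genes,
                         min_p = out$min_p, outlier = out$outlier),
              file.path(outdir, "outliers.tsv"))
    emb <- compute_embedding(filtered, method = cl$embedding,
                             seed = seed + 100L)
    write_tsv(data.frame(cell = rownames(emb$coordinates),
                         emb$coordinates),
              file.path(outdir, "embedding.tsv"))
    list(result = res, stability = stab, silhouette = sil, outliers = out,
         embedding = emb)
  })
  res <- clustered$result

  ## ---- pseudotime ----
  traj <- NULL
  if (isTRUE(cfg$pseudotime$enabled) && res$k >= 2) {
    traj <- .stage("pseudotime", outdir, resume, function() {
      coords <- if (res$method == "model_based") res$pc_scores
                else attr(compute_embedding(filtered, "pca"), "scores")
      tr <- build_trajectory(coords, res$labels)
      write_tsv(data.frame(cell = names(tr$pseudotime),
                           pseudotime = tr$pseudotime,
                           order = order(tr$cell_order)),
                file.path(outdir, "pseudotime.tsv"))
      write_tsv(data.frame(from = tr$mst_edges[, 1],
                           to = tr$mst_edges[, 2]),
                file.path(outdir, "mst_edges.tsv"))
      tr
    })
  }

  ## ---- differential expression ----
  de_cfg <- cfg$de
  de <- .stage("de", outdir, resume, function() {
    ca <- de_cfg$cluster_a %||% 1L
    cb <- de_cfg$cluster_b %||% res$k
    if (de_cfg$mode == "samseq") {
      if (ca == cb) stop("cluster_a and cluster_b must differ")
      cells <- res$labels %in% c(ca, cb)
      sub <- subset_table(filtered, cells = which(cells))
      tab <- samseq_two_class(sub, factor(res$labels[cells] == cb,
                                          c(FALSE, TRUE), c("a", "b")),
                              n_resamples = de_cfg$n_resamples,
                              n_permutations = de_cfg$n_permutations,
                              fdr_threshold = de_cfg$fdr,
                              fold_change_min = de_cfg$fc,
                              seed = seed + 300L)
    } else {
      tab <- binomial_cluster_markers(filtered, res$labels, cb,
                                      fdr_threshold = de_cfg$fdr,
                                      fold_change_min = de_cfg$fc)
    }
    write_tsv(as.data.frame(tab), file.path(outdir, "de_table.tsv"))
    write_tsv(volcano_table(tab), file.path(outdir, "volcano.tsv"))
    tab
  })

  ## ---- biomarkers ----
  bm <- cfg$biomarkers
  biomarkers <- .stage("biomarkers", outdir, resume, function() {
    out <- list()
    degs <- de$gene[de$called]
    ca <- de_cfg$cluster_a %||% 1L
    cb <- de_cfg$cluster_b %||% res$k
    feats <- utils::head(degs[order(de$q_value[de$called])],
                         bm$max_features)
    cells <- which(res$labels %in% c(ca, cb))
    if (length(feats) >= 1 && length(cells) >= 4) {
      nm <- attr(filtered, "normalized") %||% filtered$counts
      expr <- t(log2(nm[feats, cells, drop = FALSE] + 1))
      lab <- factor(ifelse(res$labels[cells] == cb, "target", "rest"),
                    c("rest", "target"))
      out$tree <- build_tree(expr, lab, inducer = bm$inducer, cp = bm$cp,
                             minsplit = bm$minsplit)
      tree_to_json(out$tree, file.path(outdir, "tree.json"))
      tree_to_dot(out$tree, file.path(outdir, "tree.dot"))
      out$cv <- cross_validate(expr, lab, inducer = bm$inducer,
                               n_folds = min(bm$folds, length(cells)),
                               seed = seed + 400L, positive = "target",
                               cp = bm$cp, minsplit = bm$minsplit)
      write_tsv(data.frame(metric = c("accuracy", "sensitivity",
                                      "specificity"),
                           value = c(out$cv$accuracy, out$cv$sensitivity,
                                     out$cv$specificity)),
                file.path(outdir, "cv_report.tsv"))
    }
    if (!is.null(bm$edges) && length(degs)) {
      net <- induced_subnetwork(read_edge_list(bm$edges, bm$min_weight),
                                degs)
      if (nrow(net))
        write_tsv(as.data.frame(centrality(net)),
                  file.path(outdir, "centrality.tsv"))
      out$network <- net
    }
    if (!is.null(bm$gmt) && length(degs)) {
      out$enrichment <- enrich(degs, read_gmt(bm$gmt), filtered$gene_ids)
      write_tsv(as.data.frame(out$enrichment),
                file.path(outdir, "enrichment.tsv"))
    }
    out
  })

  ## ---- manifest ----
  inputs <- c(cfg$counts, pp$gene_list, bm$edges, bm$gmt)
  manifest <- list(
    package = "scbiodisc",
    version = as.character(utils::packageVersion("scbiodisc")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = seed,
    stage_seeds = list(cluster = seed + 100L, de = seed + 300L,
                       biomarkers = seed + 400L),
    config = unclass(cfg),
    input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list())
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(list(input = input, filtered = filtered, clustering = clustered,
                 trajectory = traj, de = de, biomarkers = biomarkers,
                 manifest = manifest))
}
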