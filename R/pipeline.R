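#' Full-pipeline configuration
#'
#' Bundles every threshold of the analysis with its default: expressed
#' genes at FPKM > 0.5, specific genes at tau > 0.8, highly variable
#' genes at SD > 6, DPI tolerance 0, co-expression partners at edge
#' MI > 0.4, core genes at degree >= 20 with mean partner MI > 0.4,
#' network display at MI > 0.5, six expression patterns, top 30 markers
#' from a 1000-tree forest. A single seed governs all stochastic stages
#' through per-stage derived sub-seeds, so each stage is independently
#' reproducible.
#'
#' @param fpkm_cutoff expressed-gene floor (strict).
#' @param tau_cutoff specificity threshold (strict).
#' @param sd_cutoff highly-variable-gene SD threshold (strict).
#' @param dpi_tolerance DPI pruning tolerance.
#' @param edge_mi_min partner edge MI threshold (strict).
#' @param core_min_degree core-gene partner count (non-strict).
#' @param core_mean_mi core-gene mean partner MI (strict).
#' @param display_mi network display MI threshold (strict).
#' @param k_patterns expression patterns for k-means.
#' @param top_n_markers marker list size.
#' @param n_trees forest size.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(fpkm_cutoff = 0.5, tau_cutoff = 0.8,
                            sd_cutoff = 6, dpi_tolerance = 0,
                            edge_mi_min = 0.4, core_min_degree = 20L,
                            core_mean_mi = 0.4, display_mi = 0.5,
                            k_patterns = 6L, top_n_markers = 30L,
                            n_trees = 1000L, seed = 1L) {
  structure(list(fpkm_cutoff = fpkm_cutoff, tau_cutoff = tau_cutoff,
                 sd_cutoff = sd_cutoff, dpi_tolerance = dpi_tolerance,
                 edge_mi_min = edge_mi_min,
                 core_min_degree = as.integer(core_min_degree),
                 core_mean_mi = core_mean_mi, display_mi = display_mi,
                 k_patterns = as.integer(k_patterns),
                 top_n_markers = as.integer(top_n_markers),
                 n_trees = as.integer(n_trees), seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_run <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes, in order: replicate aggregation to 15 type profiles,
#' expressed-gene filtering, tau specificity with specific-gene calls,
#' highly-variable-gene selection, MI network inference on
#' replicate-level columns with DPI pruning and core-gene calling,
#' k-means expression patterns on z-scored type profiles, and
#' random-forest morph-marker ranking. Every stage's table is written
#' under `out_dir` (when given) together with a JSON run manifest
#' recording the configuration, seed, package version and per-stage
#' counts.
#'
#' @param cfg a [pipeline_config()].
#' @param expr an [expr_matrix()]; alternatively give `matrix_path` and
#'   `meta_path` to read one.
#' @param matrix_path,meta_path input files for [read_expression_matrix()]
#'   when `expr` is not supplied.
#' @param out_dir output directory; `NULL` skips writing.
#' @return invisibly, a result bundle: `filtered` (type_matrix), `tau`,
#'   `hvg`, `network`, `core`, `patterns`, `markers`, `top_markers`,
#'   `manifest`.
#' @export
run_pipeline <- function(cfg, expr = NULL, matrix_path = NULL,
                         meta_path = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(expr)) {
    if (is.null(matrix_path) || is.null(meta_path))
      stop("give either 'expr' or both 'matrix_path' and 'meta_path'",
           call. = FALSE)
    expr <- stage_run("read", read_expression_matrix(matrix_path, meta_path))
  }

  tm <- stage_run("aggregate", aggregate_types(expr))
  tm_f <- stage_run("filter", filter_expressed(tm, cfg$fpkm_cutoff))

  tau_tab <- stage_run("specificity", {
    if (nrow(tm_f$values) == 0L)
      stop("no genes pass the FPKM > ", cfg$fpkm_cutoff,
           " filter; nothing to score")
    call_specific(compute_tau(tm_f), cfg$tau_cutoff)
  })
  expr_f <- expr_matrix(expr$values[rownames(tm_f$values), , drop = FALSE],
                        expr$samples)

  hvg_tab <- stage_run("variability", select_hvg(tm_f, cfg$sd_cutoff))
  hvg_genes <- hvg_tab$gene_id[hvg_tab$selected]

  net <- stage_run("network", {
    if (length(hvg_genes) < 2L)
      stop("fewer than 2 highly variable genes; cannot build a network")
    dpi_prune(mi_matrix(expr_f, hvg_genes), cfg$dpi_tolerance)
  })
  core_tab <- stage_run("core_genes",
    call_core_genes(net, cfg$edge_mi_min, cfg$core_min_degree,
                    cfg$core_mean_mi))

  pat <- stage_run("patterns", {
    z <- suppressWarnings(zscore_rows(tm_f))
    kmeans_patterns(z, cfg$k_patterns, seed = cfg$seed + 101L)
  })

  markers_tab <- stage_run("markers",
    rank_markers(expr_f, "morph", cfg$n_trees, seed = cfg$seed + 202L))
  top <- top_markers(markers_tab, cfg$top_n_markers)

  manifest <- list(
    config = unclass(cfg),
    package_version = as.character(utils::packageVersion("aphidcoex")),
    counts = list(
      n_genes_input = nrow(expr$values),
      n_samples = ncol(expr$values),
      n_types = ncol(tm$values),
      n_expressed = nrow(tm_f$values),
      n_specific = sum(tau_tab$is_specific),
      n_hvg = length(hvg_genes),
      n_edges_unpruned = sum(!network_edges(net)$pruned),
      n_edges_display = nrow(network_edges(net, unpruned_only = TRUE,
                                           mi_min = cfg$display_mi)),
      n_core = sum(core_tab$is_core),
      pattern_sizes = as.integer(table(pat$assignments$cluster)),
      top_markers = top))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f)
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    wt(data.frame(gene_id = rownames(tm_f$values), tm_f$values,
                  check.names = FALSE), "filtered_type_matrix.tsv")
    wt(tau_tab, "tau.tsv")
    wt(hvg_tab, "hvg.tsv")
    wt(network_edges(net), "mi_edges_full.tsv")
    wt(network_edges(net, unpruned_only = TRUE), "mi_edges_pruned.tsv")
    wt(core_tab, "core_genes.tsv")
    wt(pat$assignments, "patterns.tsv")
    wt(data.frame(pattern = rownames(pat$centroids), pat$centroids,
                  check.names = FALSE), "pattern_centroids.tsv")
    wt(markers_tab, "markers.tsv")
    export_network(net, file.path(out_dir, "network_display.gml"),
                   cfg$display_mi, "gml")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  invisible(list(filtered = tm_f, tau = tau_tab, hvg = hvg_tab,
                 network = net, core = core_tab, patterns = pat,
                 markers = markers_tab, top_markers = top,
                 manifest = manifest))
}
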