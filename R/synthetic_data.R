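#' Configuration for the synthetic expression simulator
#'
#' The generator emulates the 3-genotype x 5-morph design: 15 types
#' with replicates, log-normal baseline expression on the log2 scale,
#' and three kinds of planted signal — type-specific genes (elevated in
#' exactly one type), co-expression modules driven by a shared latent
#' factor with a designated hub, and morph markers (elevated in one
#' morph across all three genotypes). Values are exponentiated to an
#' FPKM-like linear scale, so they are non-negative by construction.
#'
#' Defaults are the desk-scale study conditions used throughout the
#' package's validation: 1000 genes, 4 replicates per type, 40 specific
#' genes planted round-robin over the 15 types at 16-fold, 5 modules of
#' 25 genes at within-module correlation 0.85, 6 markers per morph at
#' 8-fold, 500 mildly sex-biased genes at 1.7-fold, and multiplicative
#' noise of 0.5 on the log2 scale.
#'
#' @param n_genes total number of genes.
#' @param n_replicates replicates per type (columns = 15 * n_replicates).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale mean and SD of
#'   per-gene baseline expression (default 3 and 2: median 8 FPKM with
#'   a realistic dynamic range).
#' @param n_specific_genes genes elevated in exactly one type.
#' @param specific_fold linear fold elevation in the target type (> 1).
#' @param n_modules,module_size planted co-expression modules.
#' @param module_rho target member-member log-scale correlation in (0,1).
#' @param n_markers_per_morph marker genes per morph (5 morphs).
#' @param marker_fold linear fold elevation in the marker's morph (> 1).
#' @param n_sex_genes sexually dimorphic genes (half elevated in the
#'   three female morphs, half in the two male morphs). These emulate
#'   the broad male/female transcriptome divergence that makes
#'   same-sex samples cluster together; 0 disables.
#' @param sex_fold linear fold elevation in the favoured sex (> 1).
#' @param noise_log2_sd SD of i.i.d. Gaussian noise on the log2 scale.
#' @param seed integer seed; the dataset is a pure function of the
#'   configuration.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000L,
                       n_replicates = 4L,
                       baseline_log2_mean = 3,
                       baseline_log2_sd = 2,
                       n_specific_genes = 40L,
                       specific_fold = 16,
                       n_modules = 5L,
                       module_size = 25L,
                       module_rho = 0.85,
                       n_markers_per_morph = 6L,
                       marker_fold = 8,
                       n_sex_genes = 500L,
                       sex_fold = 1.7,
                       noise_log2_sd = 0.5,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates = as.integer(n_replicates),
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              n_specific_genes = as.integer(n_specific_genes),
              specific_fold = specific_fold,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_rho = module_rho,
              n_markers_per_morph = as.integer(n_markers_per_morph),
              marker_fold = marker_fold,
              n_sex_genes = as.integer(n_sex_genes),
              sex_fold = sex_fold,
              noise_log2_sd = noise_log2_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L || n_replicates < 1L)
      stop("n_genes and n_replicates must be positive", call. = FALSE)
    if (baseline_log2_sd <= 0 || noise_log2_sd <= 0)
      stop("SD parameters must be strictly positive", call. = FALSE)
    if (n_specific_genes > 0L && specific_fold <= 1)
      stop("specific_fold must exceed 1", call. = FALSE)
    if (n_markers_per_morph > 0L && marker_fold <= 1)
      stop("marker_fold must exceed 1", call. = FALSE)
    if (n_sex_genes > 0L && sex_fold <= 1)
      stop("sex_fold must exceed 1", call. = FALSE)
    if (n_modules > 0L && (module_rho <= 0 || module_rho >= 1))
      stop("module_rho must lie in (0, 1)", call. = FALSE)
    planted <- n_specific_genes + n_modules * module_size +
      5L * n_markers_per_morph + n_sex_genes
    if (planted > n_genes)
      stop("infeasible config: ", planted, " planted genes exceed ",
           n_genes, " total genes", call. = FALSE)
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic 15-type expression dataset with ground truth
#'
#' Simulation happens on the log2 scale: each gene draws a log-normal
#' baseline, planted effects add log2(fold) to the affected columns,
#' module members add loading * latent-factor with the latent factor
#' drawn per column (so co-expression is estimable from replicate-level
#' data), and i.i.d. Gaussian noise is added last; the matrix is then
#' exponentiated. Module loadings are chosen so the member-member
#' log-scale correlation is approximately `module_rho`
#' (lambda = noise_sd * sqrt(rho / (1 - rho))); the hub receives a
#' four-fold loading, which makes its expression track the module's
#' latent factor far more tightly than any member's — the signature of
#' the regulator that drives the module.
#'
#' Gene roles (specific / module / marker / sex) are pairwise disjoint and
#' recorded in a machine-readable truth object used as the recovery
#' oracle for every downstream stage.
#'
#' @param cfg a [sim_config()].
#' @return list with elements `expr` (an [expr_matrix()]) and `truth`
#'   (class `synthetic_truth`: `specific_genes` named character vector
#'   gene -> target type; `module_members` list of
#'   `list(genes, hub)` per module; `marker_genes` list morph -> genes;
#'   `sex_genes` list sex -> genes).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)

  types <- expand.grid(morph = APHID_MORPHS, genotype = APHID_GENOTYPES,
                       stringsAsFactors = FALSE)[c("genotype", "morph")]
  samples <- data.frame(
    genotype  = rep(types$genotype, each = cfg$n_replicates),
    morph     = rep(types$morph, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = nrow(types)),
    stringsAsFactors = FALSE)
  samples$sample_id <- paste0(type_label(samples$genotype, samples$morph),
                              "_r", samples$replicate)
  n_col <- nrow(samples)

  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  idx <- seq_len(cfg$n_genes)
  n_spec <- cfg$n_specific_genes
  n_mod_genes <- cfg$n_modules * cfg$module_size
  n_mark <- 5L * cfg$n_markers_per_morph
  spec_idx <- idx[seq_len(n_spec)]
  mod_idx  <- idx[n_spec + seq_len(n_mod_genes)]
  mark_idx <- idx[n_spec + n_mod_genes + seq_len(n_mark)]
  sex_idx  <- idx[n_spec + n_mod_genes + n_mark + seq_len(cfg$n_sex_genes)]

  base <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                       cfg$baseline_log2_sd)
  L <- matrix(base, nrow = cfg$n_genes, ncol = n_col)

  type_labels <- type_label(types$genotype, types$morph)
  sample_types <- type_label(samples$genotype, samples$morph)

  # Type-specific genes: round-robin over the 15 types.
  specific_genes <- character(0)
  if (n_spec > 0L) {
    target <- type_labels[((seq_len(n_spec) - 1L) %% length(type_labels)) + 1L]
    for (j in seq_len(n_spec)) {
      cols <- sample_types == target[j]
      L[spec_idx[j], cols] <- L[spec_idx[j], cols] + log2(cfg$specific_fold)
    }
    specific_genes <- stats::setNames(target, gene_ids[spec_idx])
  }

  # Co-expression modules: one latent factor per module, shared across
  # all columns; first member of each module is the hub. Member loading
  # lambda gives member-member log-scale correlation ~ module_rho; the
  # hub gets 2.5x the member loading so its expression tracks the
  # latent factor far more tightly than any member's, the signature of
  # the regulator that drives the module. Module genes draw their
  # baselines 2 log2 units above the global mean (narrow spread):
  # co-expression hubs are well-expressed genes, and the absolute
  # expression swings an SD-based variability filter targets only
  # exist at such levels.
  module_members <- list()
  if (cfg$n_modules > 0L) {
    lambda <- cfg$noise_log2_sd * sqrt(cfg$module_rho / (1 - cfg$module_rho))
    base[mod_idx] <- stats::rnorm(length(mod_idx),
                                  cfg$baseline_log2_mean + 2, 0.5)
    L[mod_idx, ] <- base[mod_idx]
    for (k in seq_len(cfg$n_modules)) {
      members <- mod_idx[(k - 1L) * cfg$module_size + seq_len(cfg$module_size)]
      f <- stats::rnorm(n_col)
      load <- rep(lambda, cfg$module_size)
      load[1L] <- 4 * lambda
      L[members, ] <- L[members, ] + outer(load, f)
      module_members[[paste0("module", k)]] <-
        list(genes = gene_ids[members], hub = gene_ids[members[1L]])
    }
  }

  # Morph markers: elevated in one morph across all three genotypes.
  marker_genes <- list()
  if (cfg$n_markers_per_morph > 0L) {
    for (m in seq_along(APHID_MORPHS)) {
      genes <- mark_idx[(m - 1L) * cfg$n_markers_per_morph +
                          seq_len(cfg$n_markers_per_morph)]
      cols <- samples$morph == APHID_MORPHS[m]
      L[genes, cols] <- L[genes, cols] + log2(cfg$marker_fold)
      marker_genes[[APHID_MORPHS[m]]] <- gene_ids[genes]
    }
  }

  # Sexually dimorphic genes: half favour female morphs (WF/UWF/SF),
  # half male morphs (WM/UWM), so samples diverge more between sexes
  # than within a sex.
  sex_genes <- list()
  if (cfg$n_sex_genes > 0L) {
    sex_of_col <- morph_sex(samples$morph)
    half <- ceiling(cfg$n_sex_genes / 2)
    fem <- sex_idx[seq_len(half)]
    mal <- sex_idx[-seq_len(half)]
    L[fem, sex_of_col == "female"] <-
      L[fem, sex_of_col == "female"] + log2(cfg$sex_fold)
    L[mal, sex_of_col == "male"] <-
      L[mal, sex_of_col == "male"] + log2(cfg$sex_fold)
    sex_genes <- list(female = gene_ids[fem], male = gene_ids[mal])
  }

  L <- L + matrix(stats::rnorm(cfg$n_genes * n_col, 0, cfg$noise_log2_sd),
                  nrow = cfg$n_genes)
  values <- 2^L
  dimnames(values) <- list(gene_ids, samples$sample_id)

  truth <- structure(list(specific_genes = specific_genes,
                          module_members = module_members,
                          marker_genes = marker_genes,
                          sex_genes = sex_genes),
                     class = "synthetic_truth")
  list(expr = expr_matrix(values, samples), truth = truth)
}

#' Write a simulated dataset to disk
#'
#' Writes the matrix and metadata in the package's TSV dialect and the
#' truth record as JSON.
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory, created if absent.
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(matrix = file.path(dir, "matrix.tsv"),
             meta   = file.path(dir, "meta.tsv"),
             truth  = file.path(dir, "truth.json"))
  write_expression_matrix(dataset$expr, paths[["matrix"]], paths[["meta"]])
  tr <- unclass(dataset$truth)
  tr$specific_genes <- as.list(tr$specific_genes)  # keep gene -> type map
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
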