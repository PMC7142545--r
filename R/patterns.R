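#' Row z-scoring for pattern clustering
#'
#' Centres and scales each gene row to mean 0 and sample SD 1, the
#' normalisation used before expression-pattern clustering so that
#' clusters reflect profile shape, not magnitude. Zero-variance rows
#' cannot be scaled and are dropped with a warning.
#'
#' @param m a [type_matrix()].
#' @return a [type_matrix()] of z-scored rows; dropped gene IDs are in
#'   the `"dropped"` attribute.
#' @export
zscore_rows <- function(m) {
  stopifnot(inherits(m, "type_matrix"))
  v <- m$values
  sds <- apply(v, 1L, stats::sd)
  drop <- sds == 0
  if (any(drop))
    warning(sum(drop), " zero-variance gene row(s) dropped: ",
            paste(utils::head(rownames(v)[drop], 5L), collapse = ", "),
            if (sum(drop) > 5L) ", ..." else "")
  v <- v[!drop, , drop = FALSE]
  z <- t(scale(t(v)))            # row-wise: mean 0, sample SD 1
  dimnames(z) <- dimnames(v)
  out <- type_matrix(z, m$types)
  attr(out, "dropped") <- rownames(m$values)[drop]
  out
}

#' Cluster genes into k expression patterns
#'
#' Euclidean k-means over (typically z-scored) type profiles, taking
#' the best of `n_init` random initialisations by within-cluster sum of
#' squares. The default k = 6 matches the six expression patterns the
#' analysis reports. Raw k-means labels are arbitrary, so clusters are
#' re-indexed by descending size for stable cross-run reporting.
#'
#' @param m a [type_matrix()], rows normalised with [zscore_rows()].
#' @param k number of patterns.
#' @param n_init random initialisations tried.
#' @param seed integer seed; the assignment is deterministic given it.
#' @return list of class `pattern_assignment`: `assignments`
#'   (data.frame `gene_id`, `cluster`), `centroids` (k x N matrix),
#'   `tot_withinss`, and `init_withinss` (objective of every
#'   initialisation tried).
#' @export
kmeans_patterns <- function(m, k = 6L, n_init = 50L, seed = 1L) {
  stopifnot(inherits(m, "type_matrix"))
  v <- m$values
  if (k > nrow(v))
    stop("k = ", k, " exceeds the ", nrow(v), " genes available",
         call. = FALSE)
  set.seed(seed)
  best <- NULL
  init_withinss <- numeric(n_init)
  for (r in seq_len(n_init)) {
    fit <- stats::kmeans(v, centers = k, nstart = 1L, iter.max = 100L)
    init_withinss[r] <- fit$tot.withinss
    if (is.null(best) || fit$tot.withinss < best$tot.withinss)
      best <- fit
  }
  relabel <- order(-tabulate(best$cluster, k), seq_len(k))
  new_label <- match(best$cluster, relabel)
  centroids <- best$centers[relabel, , drop = FALSE]
  rownames(centroids) <- paste0("pattern", seq_len(k))
  structure(list(
    assignments = data.frame(gene_id = rownames(v),
                             cluster = new_label,
                             row.names = NULL,
                             stringsAsFactors = FALSE),
    centroids = centroids,
    tot_withinss = best$tot.withinss,
    init_withinss = init_withinss),
    class = "pattern_assignment")
}

#' @export
print.pattern_assignment <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  cat("pattern_assignment: ", nrow(x$assignments), " genes in ",
      length(sizes), " patterns (sizes ",
      paste(sizes, collapse = ", "), "); WCSS ",
      format(x$tot_withinss, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Dendrogram leaf orders for heatmap display
#'
#' Agglomerative clustering of genes (rows) and samples/types
#' (columns), returning the leaf orders used to arrange a heatmap.
#' Correlation distance (1 - Pearson r) is the default, the usual
#' choice for expression profiles.
#'
#' @param m a [type_matrix()] or [expr_matrix()] with >= 2 rows and
#'   columns.
#' @param distance `"correlation"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return list: `gene_order`, `sample_order` (integer index vectors),
#'   `gene_hclust`, `sample_hclust`.
#' @export
hierarchical_order <- function(m, distance = c("correlation", "euclidean"),
                               linkage = c("average", "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  v <- m$values
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("need at least 2 rows and 2 columns", call. = FALSE)
  dfun <- function(x) {
    if (distance == "euclidean") return(stats::dist(x))
    if (any(apply(x, 1L, stats::sd) == 0))
      stop("constant row/column makes correlation distance undefined",
           call. = FALSE)
    stats::as.dist(1 - stats::cor(t(x)))
  }
  gh <- stats::hclust(dfun(v), method = linkage)
  sh <- stats::hclust(dfun(t(v)), method = linkage)
  list(gene_order = gh$order, sample_order = sh$order,
       gene_hclust = gh, sample_hclust = sh)
}
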