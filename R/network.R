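# Mutual-information co-expression network with data-processing-
# inequality (DPI) pruning, in the ARACNe style: every gene pair gets a
# nonparametric MI score, and in each triangle the weakest edge is
# presumed indirect and removed.

# Equal-frequency bin labels from ranks. ties.method = "first" keeps
# the estimator invariant under strictly monotone transforms and gives
# exactly n/B observations per bin when B divides n.
.mi_bins <- function(x, B) {
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * B / length(x)) + 1L)
}

.mi_auto_bins <- function(n) max(2L, as.integer(floor(sqrt(n / 2))))

# Plug-in MI in nats from pre-binned vectors, with the Miller-Madow
# bias term subtracted and the result floored at 0. The plug-in bias
# of I = H(x) + H(y) - H(x,y) is approximately
# (K_xy - K_x - K_y + 1) / (2n) with K the nonzero-cell counts.
.mi_from_bins <- function(bx, by, B) {
  n <- length(bx)
  joint <- tabulate(bx + B * (by - 1L), B * B)
  cx <- tabulate(bx, B)
  cy <- tabulate(by, B)
  ent <- function(cnt) {
    p <- cnt[cnt > 0L] / n
    -sum(p * log(p))
  }
  mi <- ent(cx) + ent(cy) - ent(joint)
  bias <- (sum(joint > 0L) - sum(cx > 0L) - sum(cy > 0L) + 1L) / (2 * n)
  max(0, mi - bias)
}

#' Mutual information between two expression profiles
#'
#' Rank-based plug-in estimator in nats: both vectors are rank
#' transformed and discretized into B equal-frequency bins
#' (`bins = "auto"`: B = floor(sqrt(n/2)), at least 2), the plug-in MI
#' of the joint bin frequencies is computed, the Miller-Madow bias
#' estimate is subtracted, and the result is floored at 0. Because only
#' ranks enter, the estimate is invariant under strictly monotone
#' transforms of either argument and symmetric in its arguments.
#'
#' @param x,y numeric vectors of equal length n >= 8, no missing values.
#' @param bins `"auto"` or an integer number of bins >= 2.
#' @return a single non-negative MI estimate in nats. A constant input
#'   vector carries no information; it yields 0 with a warning.
#' @export
mutual_information <- function(x, y, bins = "auto") {
  n <- length(x)
  if (length(y) != n)
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (n < 8L)
    stop("need at least 8 observations, got ", n, call. = FALSE)
  if (anyNA(x) || anyNA(y))
    stop("missing values are not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input vector; returning MI = 0")
    return(0)
  }
  B <- if (identical(bins, "auto")) .mi_auto_bins(n) else as.integer(bins)
  if (B < 2L) stop("'bins' must be at least 2", call. = FALSE)
  .mi_from_bins(.mi_bins(x, B), .mi_bins(y, B), B)
}

#' All-pairs MI network for a gene set
#'
#' Computes [mutual_information()] for every unordered pair of the
#' requested genes over replicate-level sample columns (the 15
#' aggregated types alone are too few observations for a stable MI
#' estimate). Returns the complete weighted graph with no edge pruned
#' yet.
#'
#' @param m an [expr_matrix()] (replicate-level columns; a
#'   [type_matrix()] is accepted to force type-level estimation).
#' @param genes character vector of >= 2 gene IDs present in `m`.
#' @param bins passed to [mutual_information()].
#' @return an object of class `mi_network`: node list, symmetric MI
#'   matrix and a logical pruned flag per edge.
#' @export
mi_matrix <- function(m, genes, bins = "auto") {
  stopifnot(inherits(m, "expr_matrix") || inherits(m, "type_matrix"))
  missing <- setdiff(genes, rownames(m$values))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "),
         call. = FALSE)
  k <- length(genes)
  if (k < 2L) stop("need at least 2 genes", call. = FALSE)
  v <- m$values[genes, , drop = FALSE]
  n <- ncol(v)
  if (n < 8L)
    stop("need at least 8 sample columns for MI estimation", call. = FALSE)
  B <- if (identical(bins, "auto")) .mi_auto_bins(n) else as.integer(bins)
  constant <- apply(v, 1L, stats::sd) == 0
  if (any(constant))
    warning("constant gene(s) get MI 0 with all partners: ",
            paste(genes[constant], collapse = ", "))
  binned <- t(apply(v, 1L, .mi_bins, B = B))
  mi <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k - 1L)) {
    if (constant[i]) next
    for (j in seq.int(i + 1L, k)) {
      if (constant[j]) next
      mi[i, j] <- mi[j, i] <- .mi_from_bins(binned[i, ], binned[j, ], B)
    }
  }
  structure(list(nodes = genes, mi = mi,
                 pruned = matrix(FALSE, k, k,
                                 dimnames = list(genes, genes)),
                 bins = B, n_obs = n),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  k <- length(x$nodes)
  n_edge <- k * (k - 1L) / 2L
  n_pruned <- sum(x$pruned[upper.tri(x$pruned)])
  cat("mi_network: ", k, " genes, ", n_edge, " edges (",
      n_pruned, " pruned), ", x$bins, " bins over ", x$n_obs,
      " observations\n", sep = "")
  invisible(x)
}

#' Edge table of an MI network
#'
#' @param net an `mi_network`.
#' @param unpruned_only drop edges flagged by [dpi_prune()].
#' @param mi_min keep only edges with MI strictly above this value.
#' @return data.frame: `gene_a`, `gene_b`, `mi`, `pruned`.
#' @export
network_edges <- function(net, unpruned_only = FALSE, mi_min = -Inf) {
  stopifnot(inherits(net, "mi_network"))
  ut <- which(upper.tri(net$mi), arr.ind = TRUE)
  df <- data.frame(gene_a = net$nodes[ut[, 1L]],
                   gene_b = net$nodes[ut[, 2L]],
                   mi = net$mi[ut],
                   pruned = net$pruned[ut],
                   stringsAsFactors = FALSE)
  df <- df[df$mi > mi_min, , drop = FALSE]
  if (unpruned_only) df <- df[!df$pruned, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Data-processing-inequality pruning
#'
#' For every triangle (i, j, k) of unpruned edges in the input graph,
#' the edge with the strictly smallest MI is marked pruned when its MI
#' is below (1 - tolerance) times the smaller of the other two. All
#' decisions are evaluated against the input graph, so the result does
#' not depend on the order in which triangles are visited, and applying
#' the operation twice equals applying it once.
#'
#' @param net an `mi_network`.
#' @param tolerance non-negative DPI tolerance; 0 (default) is the
#'   classic strict rule.
#' @return the network with pruned flags set.
#' @export
dpi_prune <- function(net, tolerance = 0) {
  stopifnot(inherits(net, "mi_network"))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop("'tolerance' must be a single non-negative number", call. = FALSE)
  M <- net$mi
  k <- nrow(M)
  Mp <- M
  Mp[net$pruned] <- -Inf       # absent edges cannot form triangles
  diag(Mp) <- -Inf
  pruned <- net$pruned
  for (i in seq_len(k - 1L)) {
    mi_i <- Mp[i, ]
    for (j in seq.int(i + 1L, k)) {
      if (!is.finite(Mp[i, j])) next
      w <- M[i, j]
      mi_j <- Mp[j, ]
      hit <- mi_i > w & mi_j > w & w < (1 - tolerance) * pmin(mi_i, mi_j)
      if (any(hit)) pruned[i, j] <- pruned[j, i] <- TRUE
    }
  }
  net$pruned <- pruned
  net
}

#' Call core (hub) genes of a pruned network
#'
#' A gene's co-expressed partners are its unpruned neighbours with edge
#' MI strictly above `edge_mi_min`. The gene is a core gene when it has
#' at least `min_degree` such partners (non-strict) and the mean MI over
#' those edges strictly exceeds `mean_mi_min`.
#'
#' @param net a DPI-pruned `mi_network`.
#' @param edge_mi_min partner edge threshold (strict), default 0.4.
#' @param min_degree minimum partner count (non-strict), default 20.
#' @param mean_mi_min mean partner-edge MI threshold (strict),
#'   default 0.4.
#' @return data.frame: `gene_id`, `degree`, `mean_mi` (NA for isolated
#'   genes), `is_core`.
#' @export
call_core_genes <- function(net, edge_mi_min = 0.4, min_degree = 20L,
                            mean_mi_min = 0.4) {
  stopifnot(inherits(net, "mi_network"))
  if (min_degree < 0 || edge_mi_min < 0 || mean_mi_min < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  A <- net$mi
  A[net$pruned] <- 0
  diag(A) <- 0
  partner <- A > edge_mi_min
  degree <- rowSums(partner)
  mi_sum <- rowSums(A * partner)
  mean_mi <- ifelse(degree > 0, mi_sum / degree, NA_real_)
  data.frame(gene_id = net$nodes,
             degree = as.integer(degree),
             mean_mi = mean_mi,
             is_core = degree >= min_degree &
               !is.na(mean_mi) & mean_mi > mean_mi_min,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a network for display
#'
#' Writes the unpruned edges with MI strictly above `display_mi_min`
#' (default 0.5, the display threshold for the co-expression figure).
#' The GML form carries each node's degree in the displayed graph, the
#' datum behind connectivity colouring; the edge-list form is a
#' three-column TSV.
#'
#' @param net a pruned `mi_network`.
#' @param path output file.
#' @param display_mi_min strict MI display threshold.
#' @param format `"edge_list_tsv"` or `"gml"`.
#' @return invisibly, the path written.
#' @export
export_network <- function(net, path, display_mi_min = 0.5,
                           format = c("edge_list_tsv", "gml")) {
  format <- match.arg(format)
  edges <- network_edges(net, unpruned_only = TRUE,
                         mi_min = display_mi_min)
  if (format == "edge_list_tsv") {
    utils::write.table(edges[c("gene_a", "gene_b", "mi")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges[c("gene_a", "gene_b", "mi")], directed = FALSE,
      vertices = data.frame(name = net$nodes))
    igraph::E(g)$weight <- edges$mi
    igraph::V(g)$degree <- igraph::degree(g)
    igraph::write_graph(g, path, format = "gml")
  }
  invisible(path)
}
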