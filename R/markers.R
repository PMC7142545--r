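#' Rank genes as morph markers with a random forest
#'
#' Trains a Breiman random forest on replicate-level samples
#' (observations) by gene expression (features), labelled by morph
#' (default, 5 classes) or by the full (genotype, morph) type. Each of
#' `n_trees` trees is grown on a bootstrap resample with floor(sqrt(p))
#' candidate features per split and the Gini impurity criterion. Two
#' importances are reported per gene: mean decrease in Gini impurity
#' (total impurity reduction attributed to the gene) and mean decrease
#' in out-of-bag accuracy when the gene's values are permuted.
#'
#' @param m an [expr_matrix()] with at least 2 samples per class.
#' @param label `"morph"` or `"type"` class labels.
#' @param n_trees trees in the ensemble (default 1000).
#' @param seed integer seed; the ranking is deterministic given it.
#' @return data.frame of all genes sorted by `rank_gini`: `gene_id`,
#'   `mean_decrease_gini`, `mean_decrease_accuracy`, `rank_gini` (ties
#'   broken by gene order).
#' @export
rank_markers <- function(m, label = c("morph", "type"),
                         n_trees = 1000L, seed = 1L) {
  label <- match.arg(label)
  stopifnot(inherits(m, "expr_matrix"))
  if (nrow(m$values) == 0L) stop("no genes in matrix", call. = FALSE)
  y <- factor(if (label == "morph") m$samples$morph else m$samples$type)
  if (nlevels(y) < 2L)
    stop("need at least 2 label classes", call. = FALSE)
  small <- table(y) < 2L
  if (any(small))
    stop("class(es) with fewer than 2 samples: ",
         paste(names(small)[small], collapse = ", "), call. = FALSE)
  x <- t(m$values)
  # randomForest mangles non-syntactic feature names; keep a map.
  gene_ids <- colnames(x)
  colnames(x) <- paste0("f", seq_along(gene_ids))
  set.seed(seed)
  rf <- randomForest::randomForest(x = x, y = y, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf)
  gini <- imp[, "MeanDecreaseGini"]
  acc <- imp[, "MeanDecreaseAccuracy"]
  rank_gini <- order(order(-gini, seq_along(gini)))
  out <- data.frame(gene_id = gene_ids,
                    mean_decrease_gini = as.numeric(gini),
                    mean_decrease_accuracy = as.numeric(acc),
                    rank_gini = rank_gini,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$rank_gini), ]
}

#' Top marker genes by Gini importance
#'
#' @param rankings output of [rank_markers()].
#' @param top_n markers to keep (default 30, the reported marker-list
#'   size); if larger than the gene count, all genes are returned with
#'   a warning.
#' @return character vector of gene IDs in rank order.
#' @export
top_markers <- function(rankings, top_n = 30L) {
  if (top_n < 1L) stop("'top_n' must be positive", call. = FALSE)
  if (top_n > nrow(rankings)) {
    warning("top_n = ", top_n, " exceeds the ", nrow(rankings),
            " ranked genes; returning all")
    top_n <- nrow(rankings)
  }
  rankings$gene_id[rankings$rank_gini <= top_n]
}
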