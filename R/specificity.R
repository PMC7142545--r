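#' The tau type-specificity index
#'
#' For each gene, tau = sum_{i=1..N}(1 - x_i) / (N - 1) where N is the
#' number of type columns and x_i is the gene's expression in type i
#' divided by its maximum across all types. tau is 0 for a gene
#' expressed uniformly across types and 1 for a gene expressed in a
#' single type; it depends only on the expression profile up to a
#' positive per-gene rescaling.
#'
#' By default tau is computed on the linear FPKM-scale values as
#' handed in; specificity indices are scale-sensitive, so callers who
#' want a compressed dynamic range can pass `log2_scale = TRUE` to
#' apply log2(v + 1) first.
#'
#' @param m a [type_matrix()], already restricted to expressed genes
#'   ([filter_expressed()]) so every gene has a positive maximum.
#' @param log2_scale compute tau on log2(v + 1) instead of linear
#'   values.
#' @return data.frame with one row per gene: `gene_id`, `tau`,
#'   `max_type`, `max_genotype`, `max_morph`, `max_tied` (TRUE when the
#'   argmax was tied and the first column in order was taken) and
#'   `is_specific` (NA until [call_specific()] sets it).
#' @export
compute_tau <- function(m, log2_scale = FALSE) {
  stopifnot(inherits(m, "type_matrix"))
  v <- m$values
  if (ncol(v) < 2L)
    stop("tau needs at least 2 type columns", call. = FALSE)
  if (log2_scale) v <- log2(v + 1)
  mx <- apply(v, 1L, max)
  if (any(mx <= 0)) {
    bad <- rownames(v)[mx <= 0][1L]
    stop("gene '", bad, "' has no positive expression in any type; ",
         "run filter_expressed() first", call. = FALSE)
  }
  x <- v / mx
  n <- ncol(v)
  tau <- rowSums(1 - x) / (n - 1L)
  arg <- apply(v, 1L, which.max)           # first column wins ties
  tied <- apply(v, 1L, function(r) sum(r == max(r)) > 1L)
  data.frame(gene_id = rownames(v),
             tau = tau,
             max_type = colnames(v)[arg],
             max_genotype = m$types$genotype[arg],
             max_morph = m$types$morph[arg],
             max_tied = tied,
             is_specific = NA,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Call type-specifically expressed genes
#'
#' Flags genes whose tau strictly exceeds the cutoff (default 0.8) as
#' type-specifically expressed; a gene sitting exactly at the cutoff is
#' not called.
#'
#' @param results output of [compute_tau()].
#' @param tau_cutoff specificity threshold in \[0, 1\], strict.
#' @return `results` with `is_specific` filled in, plus a
#'   `"morph_tally"` attribute: number of specific genes per morph of
#'   the maximum-expression type.
#' @export
call_specific <- function(results, tau_cutoff = 0.8) {
  if (!is.numeric(tau_cutoff) || length(tau_cutoff) != 1L ||
      tau_cutoff < 0 || tau_cutoff > 1)
    stop("'tau_cutoff' must be a single number in [0, 1]", call. = FALSE)
  results$is_specific <- results$tau > tau_cutoff
  tally <- table(factor(results$max_morph[results$is_specific],
                        levels = APHID_MORPHS))
  attr(results, "morph_tally") <- tally
  results
}
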