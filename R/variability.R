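#' Select highly variable genes by standard deviation
#'
#' Computes each gene's sample standard deviation (denominator N - 1)
#' across the matrix columns and flags genes whose SD strictly exceeds
#' the cutoff. The default cutoff of 6 is calibrated to linear
#' FPKM-scale values; pass the matrix on the scale you intend.
#'
#' @param m a [type_matrix()] (default unit of analysis) or an
#'   [expr_matrix()] to select on replicate-level columns.
#' @param sd_cutoff non-negative SD threshold, strict.
#' @return data.frame: `gene_id`, `sd`, `selected`.
#' @export
select_hvg <- function(m, sd_cutoff = 6) {
  stopifnot(inherits(m, "type_matrix") || inherits(m, "expr_matrix"))
  if (!is.numeric(sd_cutoff) || length(sd_cutoff) != 1L || sd_cutoff < 0)
    stop("'sd_cutoff' must be a single non-negative number", call. = FALSE)
  v <- m$values
  if (ncol(v) < 2L)
    stop("standard deviation needs at least 2 columns", call. = FALSE)
  sds <- apply(v, 1L, stats::sd)
  data.frame(gene_id = rownames(v),
             sd = sds,
             selected = sds > sd_cutoff,
             row.names = NULL,
             stringsAsFactors = FALSE)
}
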