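# Controlled vocabularies for the 3 x 5 experimental design.
APHID_GENOTYPES <- c("F1", "I18", "BK11")
APHID_MORPHS    <- c("WF", "UWF", "SF", "WM", "UWM")

#' Sex and wing state implied by a morph code
#'
#' The five pea-aphid morphs are winged asexual female (WF), wingless
#' asexual female (UWF), wingless sexual female (SF), winged male (WM)
#' and wingless male (UWM). Sex and wing state are therefore functions
#' of the morph code alone.
#'
#' @param morph character vector of morph codes.
#' @return character vector, `"female"`/`"male"` for [morph_sex()],
#'   `"winged"`/`"wingless"` for [morph_wing()].
#' @export
morph_sex <- function(morph) {
  stopifnot(all(morph %in% APHID_MORPHS))
  ifelse(morph %in% c("WF", "UWF", "SF"), "female", "male")
}

#' @rdname morph_sex
#' @export
morph_wing <- function(morph) {
  stopifnot(all(morph %in% APHID_MORPHS))
  ifelse(morph %in% c("WF", "WM"), "winged", "wingless")
}

#' Type label for (genotype, morph) pairs
#' @param genotype,morph character vectors of equal length.
#' @return character vector like `"F1_WF"`.
#' @export
type_label <- function(genotype, morph) paste(genotype, morph, sep = "_")

validate_sample_meta <- function(samples) {
  required <- c("sample_id", "genotype", "morph", "replicate")
  missing <- setdiff(required, names(samples))
  if (length(missing))
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample IDs in metadata: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  bad_g <- setdiff(unique(samples$genotype), APHID_GENOTYPES)
  if (length(bad_g))
    stop("unknown genotype(s): ", paste(bad_g, collapse = ", "),
         "; expected one of ", paste(APHID_GENOTYPES, collapse = ", "),
         call. = FALSE)
  bad_m <- setdiff(unique(samples$morph), APHID_MORPHS)
  if (length(bad_m))
    stop("unknown morph(s): ", paste(bad_m, collapse = ", "),
         "; expected one of ", paste(APHID_MORPHS, collapse = ", "),
         call. = FALSE)
  rep <- samples$replicate
  if (!is.numeric(rep) || any(rep != floor(rep)) || any(rep < 1))
    stop("replicate indices must be positive integers", call. = FALSE)
  samples$replicate <- as.integer(rep)
  samples$type <- type_label(samples$genotype, samples$morph)
  samples
}

#' Construct a validated expression matrix
#'
#' Bundles a non-negative gene x sample numeric matrix (FPKM scale) with
#' per-sample metadata (genotype, morph, replicate). Column order of
#' `values` must follow the row order of `samples`.
#'
#' @param values numeric matrix, genes in rows (rownames = gene IDs),
#'   samples in columns.
#' @param samples data.frame with columns `sample_id`, `genotype`,
#'   `morph`, `replicate`.
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, samples) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if (nrow(values) > 0L && is.null(rownames(values)))
    stop("'values' must carry gene IDs as rownames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ID(s): ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "), call. = FALSE)
  samples <- validate_sample_meta(as.data.frame(samples))
  if (ncol(values) != nrow(samples))
    stop("matrix has ", ncol(values), " columns but metadata describes ",
         nrow(samples), " samples", call. = FALSE)
  if (!is.null(colnames(values)) &&
      !identical(colnames(values), samples$sample_id))
    stop("matrix column names do not match metadata sample_id order",
         call. = FALSE)
  colnames(values) <- samples$sample_id
  if (any(!is.finite(values)))
    stop("expression values must all be finite", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  structure(list(values = values, samples = samples),
            class = "expr_matrix")
}

#' Construct a type-level matrix
#'
#' A gene x type matrix where each column aggregates the replicate
#' columns of one (genotype, morph) type. The number of type columns N
#' is the N of the tau specificity formula.
#'
#' @param values numeric gene x type matrix, colnames = type labels.
#' @param types data.frame with columns `genotype`, `morph` in column
#'   order.
#' @return an object of class `type_matrix`.
#' @export
type_matrix <- function(values, types) {
  stopifnot(is.matrix(values), is.numeric(values))
  types <- as.data.frame(types)
  stopifnot(all(c("genotype", "morph") %in% names(types)),
            nrow(types) == ncol(values))
  types$type <- type_label(types$genotype, types$morph)
  if (anyDuplicated(types$type))
    stop("duplicate type columns", call. = FALSE)
  if (nrow(types) > 15L)
    stop("at most 15 (genotype, morph) types are possible", call. = FALSE)
  colnames(values) <- types$type
  structure(list(values = values, types = types), class = "type_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples (", length(unique(x$samples$type)), " types)\n", sep = "")
  invisible(x)
}

#' @export
print.type_matrix <- function(x, ...) {
  cat("type_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " types\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dim.type_matrix <- function(x) dim(x$values)

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix with sample metadata
#'
#' The matrix file is delimited text (tab by default, comma when the
#' extension is `.csv`), first column gene IDs, header row of sample
#' IDs. The metadata file must describe every sample column with
#' `sample_id`, `genotype`, `morph`, `replicate`. Columns are reordered
#' to follow the metadata row order.
#'
#' @param matrix_path path to the expression matrix file.
#' @param meta_path path to the sample metadata table.
#' @return an [expr_matrix()].
#' @export
read_expression_matrix <- function(matrix_path, meta_path) {
  raw <- utils::read.table(matrix_path, sep = delim_for(matrix_path),
                           header = TRUE, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2L)
    stop("matrix file has no sample columns", call. = FALSE)
  gene_ids <- raw[[1L]]
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ID(s) in ", matrix_path, ": ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "),
         call. = FALSE)
  cells <- as.matrix(raw[-1L])
  values <- suppressWarnings(
    matrix(as.numeric(cells), nrow = nrow(cells),
           dimnames = list(gene_ids, colnames(cells))))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop("non-numeric cell '", cells[bad[1L], bad[2L]], "' at gene '",
         gene_ids[bad[1L]], "', sample '", colnames(cells)[bad[2L]], "'",
         call. = FALSE)
  }
  samples <- utils::read.table(meta_path, sep = delim_for(meta_path),
                               header = TRUE, stringsAsFactors = FALSE)
  orphan <- setdiff(colnames(values), samples$sample_id)
  if (length(orphan))
    stop("sample column(s) missing from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  samples <- samples[samples$sample_id %in% colnames(values), , drop = FALSE]
  expr_matrix(values[, samples$sample_id, drop = FALSE], samples)
}

#' Write an expression matrix and its metadata as TSV
#'
#' @param em an [expr_matrix()].
#' @param matrix_path,meta_path output paths (tab-delimited).
#' @export
write_expression_matrix <- function(em, matrix_path, meta_path) {
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta <- em$samples[c("sample_id", "genotype", "morph", "replicate")]
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' Keep genes expressed above an FPKM floor
#'
#' A gene counts as expressed when its maximum value across all columns
#' is strictly greater than `fpkm_cutoff` (default 0.5 FPKM). The
#' column set is unchanged; the operation is idempotent.
#'
#' @param m an [expr_matrix()] or [type_matrix()].
#' @param fpkm_cutoff non-negative expression floor, strict comparison.
#' @return the same class as `m`, restricted to expressed genes.
#' @export
filter_expressed <- function(m, fpkm_cutoff = 0.5) {
  if (!is.numeric(fpkm_cutoff) || length(fpkm_cutoff) != 1L ||
      fpkm_cutoff < 0)
    stop("'fpkm_cutoff' must be a single non-negative number",
         call. = FALSE)
  UseMethod("filter_expressed")
}

#' @export
filter_expressed.expr_matrix <- function(m, fpkm_cutoff = 0.5) {
  keep <- apply(m$values, 1L, max) > fpkm_cutoff
  expr_matrix(m$values[keep, , drop = FALSE], m$samples)
}

#' @export
filter_expressed.type_matrix <- function(m, fpkm_cutoff = 0.5) {
  keep <- apply(m$values, 1L, max) > fpkm_cutoff
  type_matrix(m$values[keep, , drop = FALSE], m$types)
}

#' Aggregate replicate columns into one column per type
#'
#' @param em an [expr_matrix()].
#' @param method replicate aggregate, `"mean"` (default) or `"median"`.
#' @return a [type_matrix()] with one column per distinct
#'   (genotype, morph) pair, in first-appearance order.
#' @export
aggregate_types <- function(em, method = c("mean", "median")) {
  method <- match.arg(method)
  stopifnot(inherits(em, "expr_matrix"))
  if (nrow(em$values) == 0L)
    stop("cannot aggregate an empty matrix", call. = FALSE)
  types <- unique(em$samples[c("genotype", "morph")])
  labels <- type_label(types$genotype, types$morph)
  fun <- if (method == "mean") rowMeans else
    function(v) apply(v, 1L, stats::median)
  cols <- vapply(labels, function(tp) {
    idx <- em$samples$type == tp
    fun(em$values[, idx, drop = FALSE])
  }, numeric(nrow(em$values)))
  values <- matrix(cols, nrow = nrow(em$values),
                   dimnames = list(rownames(em$values), labels))
  type_matrix(values, types)
}

#' log2-transform expression values with a pseudocount
#'
#' Replaces each value v by log2(v + pseudocount); monotone and
#' order-preserving within each gene.
#'
#' @param m an [expr_matrix()] or [type_matrix()].
#' @param pseudocount positive offset added before the log (default 1).
#' @export
log_transform <- function(m, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount <= 0)
    stop("'pseudocount' must be a single positive number", call. = FALSE)
  UseMethod("log_transform")
}

#' @export
log_transform.expr_matrix <- function(m, pseudocount = 1) {
  expr_matrix(log2(m$values + pseudocount), m$samples)
}

#' @export
log_transform.type_matrix <- function(m, pseudocount = 1) {
  type_matrix(log2(m$values + pseudocount), m$types)
}

#' Percentage of reads mapped
#'
#' The mapping-rate arithmetic of a read-alignment summary table:
#' 100 * mapped / total, rounded to the nearest 0.1.
#'
#' @param total_reads positive integer vector of sequenced reads.
#' @param mapped_reads non-negative integer vector, elementwise at most
#'   `total_reads`.
#' @return numeric vector of percentages in \[0, 100\].
#' @export
mapping_rate <- function(total_reads, mapped_reads) {
  if (any(total_reads <= 0))
    stop("'total_reads' must be positive", call. = FALSE)
  if (any(mapped_reads < 0))
    stop("'mapped_reads' must be non-negative", call. = FALSE)
  if (any(mapped_reads > total_reads))
    stop("'mapped_reads' cannot exceed 'total_reads'", call. = FALSE)
  round(100 * mapped_reads / total_reads, 1L)
}

#' Published per-type read-mapping summary
#'
#' The read-alignment summary for the 15 pea-aphid types (total reads,
#' mapped reads and printed mapping rate per type), shipped as a
#' plain-text fixture for worked-example checks of [mapping_rate()].
#'
#' @return data.frame with columns `type`, `total_reads`,
#'   `mapped_reads`, `mapping_rate_printed`.
#' @export
mapping_stats <- function() {
  path <- system.file("extdata", "mapping_stats.tsv",
                      package = "aphidcoex", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
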