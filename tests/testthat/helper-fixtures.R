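# Shared fixture builders. Everything is generated in code; no files
# ship with the tests.

# Metadata for the full 15-type design with n_rep replicates each.
full_meta <- function(n_rep = 1L) {
  types <- expand.grid(morph = c("WF", "UWF", "SF", "WM", "UWM"),
                       genotype = c("F1", "I18", "BK11"),
                       stringsAsFactors = FALSE)[c("genotype", "morph")]
  meta <- data.frame(
    genotype  = rep(types$genotype, each = n_rep),
    morph     = rep(types$morph, each = n_rep),
    replicate = rep(seq_len(n_rep), times = nrow(types)),
    stringsAsFactors = FALSE)
  meta$sample_id <- paste0(meta$genotype, "_", meta$morph, "_r",
                           meta$replicate)
  meta[c("sample_id", "genotype", "morph", "replicate")]
}

# Wrap a bare numeric matrix into an expr_matrix, inventing gene IDs
# and taking the first ncol(v) rows of the replicate grid as metadata.
toy_expr <- function(v, n_rep = 1L) {
  meta <- full_meta(n_rep)[seq_len(ncol(v)), , drop = FALSE]
  if (is.null(rownames(v)))
    rownames(v) <- sprintf("t%03d", seq_len(nrow(v)))
  colnames(v) <- meta$sample_id
  expr_matrix(v, meta)
}

# A type_matrix over all 15 types from a bare matrix.
toy_type_matrix <- function(v) {
  types <- expand.grid(morph = c("WF", "UWF", "SF", "WM", "UWM"),
                       genotype = c("F1", "I18", "BK11"),
                       stringsAsFactors = FALSE)[c("genotype", "morph")]
  types <- types[seq_len(ncol(v)), , drop = FALSE]
  if (is.null(rownames(v)))
    rownames(v) <- sprintf("t%03d", seq_len(nrow(v)))
  type_matrix(v, types)
}

# Hand-built mi_network for DPI and core-gene unit tests.
toy_network <- function(M, nodes = NULL) {
  if (is.null(nodes)) nodes <- sprintf("n%02d", seq_len(nrow(M)))
  dimnames(M) <- list(nodes, nodes)
  structure(list(nodes = nodes, mi = M,
                 pruned = matrix(FALSE, nrow(M), ncol(M),
                                 dimnames = dimnames(M)),
                 bins = NA_integer_, n_obs = NA_integer_),
            class = "mi_network")
}

# Exhaustive brute-force DPI over all triangles; the independent oracle
# the vectorised implementation is checked against.
dpi_brute_force <- function(M, tolerance = 0) {
  k <- nrow(M)
  pruned <- matrix(FALSE, k, k)
  for (tri in utils::combn(k, 3L, simplify = FALSE)) {
    i <- tri[1L]; j <- tri[2L]; l <- tri[3L]
    w <- c(M[i, j], M[i, l], M[j, l])
    lo <- which(w == min(w))
    if (length(lo) > 1L) next                    # no strict minimum
    if (min(w) < (1 - tolerance) * min(w[-lo])) {
      pair <- list(c(i, j), c(i, l), c(j, l))[[lo]]
      pruned[pair[1L], pair[2L]] <- pruned[pair[2L], pair[1L]] <- TRUE
    }
  }
  pruned
}

# Literal transcription of the tau formula, kept deliberately naive.
tau_literal <- function(v) {
  x <- v / max(v)
  sum(1 - x) / (length(v) - 1)
}
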