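#' @keywords internal
"_PACKAGE"

# Canonical edge representation used throughout: two endpoint columns with
# gene_a < gene_b lexicographically, plus a "gene_a|gene_b" id string.

#' Canonicalize gene pairs
#'
#' Orders each pair lexicographically so that `gene_a < gene_b`. Self-pairs
#' are not removed here; callers decide.
#'
#' @param gene_a,gene_b character vectors of equal length.
#' @return data.frame with columns `gene_a`, `gene_b`.
#' @export
canonicalize_pairs <- function(gene_a, gene_b) {
  gene_a <- trimws(as.character(gene_a))
  gene_b <- trimws(as.character(gene_b))
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]
  gene_a[swap] <- gene_b[swap]
  gene_b[swap] <- tmp
  data.frame(gene_a = gene_a, gene_b = gene_b, stringsAsFactors = FALSE)
}

#' Edge id strings from endpoint columns
#' @param edges data.frame with canonical `gene_a`, `gene_b` columns.
#' @return character vector "gene_a|gene_b".
#' @export
edge_ids <- function(edges) {
  paste(edges$gene_a, edges$gene_b, sep = "|")
}

#' Split edge ids back into endpoint columns
#' @param ids character vector of "gene_a|gene_b" ids.
#' @return data.frame with `gene_a`, `gene_b`.
#' @export
split_edge_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(
    gene_a = vapply(parts, `[`, character(1), 1L),
    gene_b = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

# Multivariate normal draws via the Cholesky factor; a pure function of the
# RNG state so every generator is reproducible from its seed.
rmvnorm_chol <- function(n, sigma, mean = 0) {
  p <- nrow(sigma)
  L <- chol(sigma)
  z <- matrix(stats::rnorm(n * p), n, p)
  sweep(z %*% L, 2, rep_len(mean, p), "+")
}

ssn_log <- function(...) {
  message("[ssnet] ", sprintf(...))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Write a data frame as headered TSV
#' @param x data.frame. @param path output file.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV into a data frame
#' @param path input file.
#' @export
read_tsv_file <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix (genes x samples) as TSV
#'
#' First column `gene_id`, remaining columns one per sample.
#' @param mat numeric matrix with gene rownames and sample colnames.
#' @param path output file.
#' @export
write_expression_tsv <- function(mat, path) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix TSV (genes in rows, first column gene id)
#' @param path input file.
#' @return numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  gid <- trimws(as.character(df[[1]]))
  if (anyDuplicated(gid)) stopf("duplicate gene ids in %s", path)
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stopf("non-numeric expression values in %s", path)
  rownames(mat) <- gid
  mat
}
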