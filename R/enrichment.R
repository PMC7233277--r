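# Hypergeometric over-representation of key genes in pathway gene sets.
# With N background genes, M key genes, n pathway genes (restricted to the
# background) and m overlap, the enrichment p-value is
#   p(m, M, N, n) = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M, n-i) / C(N,n)
#                 = P(X >= m),  X ~ Hypergeometric(N, M, n).

#' Hypergeometric upper-tail p-value
#'
#' Computed directly from the display formula with log-binomials
#' (`lchoose`) for numerical stability; equals `P(X >= m)` for a
#' hypergeometric draw of `n` from `N` with `M` marked.
#'
#' @param m overlap of key genes with the pathway.
#' @param M number of key genes.
#' @param N total genes in the background network.
#' @param n pathway size (within the background).
#' @return p-value in \[0, 1\]; `m = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(m, M, N, n) {
  if (M > N || n > N) stopf("require M <= N and n <= N")
  if (m > min(M, n)) stopf("require m <= min(M, n)")
  if (m < 0 || M < 0 || n < 0) stopf("negative counts")
  if (m == 0) return(1)
  i <- m:min(M, n)
  # terms C(M,i) C(N-M, n-i) / C(N,n), valid automatically via lchoose = -Inf
  lt <- lchoose(M, i) + lchoose(N - M, n - i) - lchoose(N, n)
  min(1, max(0, sum(exp(lt))))
}

#' Pathway over-representation of a key-gene set
#'
#' One hypergeometric test per pathway. Pathway gene sets are intersected
#' with the background genes before counting, matching the definition of
#' `N` as the background-network total. Pathways with an empty background
#' intersection are skipped with a log entry; pathways with zero overlap
#' are reported with p = 1, not dropped. Raw p-values are thresholded at
#' `alpha` (no multiple-testing correction by default; `adjust = "BH"`
#' adds Benjamini-Hochberg adjusted p-values and applies `alpha` to them).
#'
#' @param key_genes character vector, subset of `background_genes`.
#' @param gene_sets a `gene_set_collection` (named list of gene vectors).
#' @param background_genes the background-network gene universe.
#' @param alpha enrichment level, default 0.05 (strict `<`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted by ascending p with columns `pathway`, `N`,
#'   `M`, `n`, `m`, `p` (and `p_adj` when adjusted), `enriched`.
#' @export
enrich_pathways <- function(key_genes, gene_sets, background_genes,
                            alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  extra <- setdiff(key_genes, background_genes)
  if (length(extra))
    stopf("%d key genes are not in the background gene universe", length(extra))
  N <- length(unique(background_genes))
  M <- length(unique(key_genes))
  rows <- lapply(names(gene_sets), function(pw) {
    pw_genes <- intersect(gene_sets[[pw]], background_genes)
    if (!length(pw_genes)) {
      ssn_log("pathway '%s' has no genes in the background; skipped", pw)
      return(NULL)
    }
    n <- length(pw_genes)
    m <- length(intersect(key_genes, pw_genes))
    data.frame(pathway = pw, N = N, M = M, n = n, m = m,
               p = hypergeom_pvalue(m, M, N, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stopf("no pathway overlaps the background genes")
  out <- out[order(out$p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adj <- stats::p.adjust(out$p, method = "BH")
    out$enriched <- out$p_adj < alpha
  } else {
    out$enriched <- out$p < alpha
  }
  out
}
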