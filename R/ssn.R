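# Sample-specific network core: reference co-expression network over normal
# samples, and the per-tumor delta-PCC differential network with the Z-test
# null. The per-edge statistic for one added sample sd_x is
#   delta = PCC_{n+1} - PCC_n,   Z = delta / ((1 - PCC_n^2) / (n - 1)),
# with (1 - PCC_n^2)/(n - 1) the null standard deviation of delta and a
# two-sided standard-normal p-value.

#' Pearson product-moment correlation with degeneracy flagging
#'
#' Standard Pearson correlation, clamped to \[-1, 1\] against round-off.
#' If either vector has zero variance the result is `NA` (the degenerate
#' flag) rather than a silent `NaN`.
#'
#' @param x,y numeric vectors of equal length (>= 3), finite.
#' @return correlation in \[-1, 1\], or `NA` for degenerate input.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stopf("pearson: unequal lengths")
  if (length(x) < 3) stopf("pearson: need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("pearson: non-finite values")
  xc <- x - mean(x)
  yc <- y - mean(y)
  vx <- sum(xc^2)
  vy <- sum(yc^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  r <- sum(xc * yc) / sqrt(vx * vy)
  min(1, max(-1, r))
}

#' Build the reference co-expression network
#'
#' Computes `PCC_n` for every background edge across all reference (normal)
#' samples, and caches the per-gene and per-edge sufficient statistics that
#' make adding one tumor sample an O(1)-per-edge update.
#'
#' Edges whose genes are missing from the matrix are dropped with a logged
#' count (default) or raise an error. Degenerate edges (a zero-variance
#' gene, or `|PCC_n| >= 1 - eps`) are kept in the table but marked
#' untestable and excluded from significance testing.
#'
#' @param expr_ref numeric matrix, genes x reference samples, gene rownames.
#' @param bg a `background_network`.
#' @param on_missing `"drop"` (default) drops edges with absent genes,
#'   `"error"` fails.
#' @param transform `"none"` (default) or `"log2p1"` (log2(x+1) before
#'   correlation).
#' @param eps degeneracy guard: edges with `|PCC_n| >= 1 - eps` are not
#'   tested. Default 1e-6.
#' @return object of class `reference_network`.
#' @export
build_reference <- function(expr_ref, bg, on_missing = c("drop", "error"),
                            transform = c("none", "log2p1"), eps = 1e-6) {
  on_missing <- match.arg(on_missing)
  transform <- match.arg(transform)
  if (is.null(rownames(expr_ref))) stopf("expr_ref needs gene rownames")
  if (ncol(expr_ref) < 3) stopf("need at least 3 reference samples")
  if (!all(is.finite(expr_ref))) stopf("non-finite expression values")
  if (transform == "log2p1") expr_ref <- log2(expr_ref + 1)

  edges <- bg$edges
  present <- edges$gene_a %in% rownames(expr_ref) &
             edges$gene_b %in% rownames(expr_ref)
  if (!all(present)) {
    if (on_missing == "error")
      stopf("%d background edges reference genes absent from the expression matrix",
            sum(!present))
    ssn_log("dropping %d background edges with genes absent from the expression matrix",
            sum(!present))
    edges <- edges[present, , drop = FALSE]
  }
  if (!nrow(edges)) stopf("no background edges left after gene matching")
  genes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  X <- expr_ref[genes, , drop = FALSE]
  n <- ncol(X)

  ia <- match(edges$gene_a, genes)
  ib <- match(edges$gene_b, genes)
  S <- rowSums(X)
  Q <- rowSums(X^2)
  C <- rowSums(X[ia, , drop = FALSE] * X[ib, , drop = FALSE])

  mu <- S / n
  Xc <- X - mu
  ss <- rowSums(Xc^2)
  num <- rowSums(Xc[ia, , drop = FALSE] * Xc[ib, , drop = FALSE])
  den <- sqrt(ss[ia] * ss[ib])
  pcc <- ifelse(den > 0, num / den, NA_real_)
  pcc <- pmin(1, pmax(-1, pcc))
  testable <- !is.na(pcc) & abs(pcc) < 1 - eps
  n_bad <- sum(!testable)
  if (n_bad)
    ssn_log("%d degenerate edges (zero variance or |PCC_n| ~ 1) excluded from testing",
            n_bad)

  structure(
    list(
      edges = data.frame(edges, pcc_n = pcc, testable = testable,
                         row.names = NULL, stringsAsFactors = FALSE),
      background = bg,
      genes = genes,
      n = n,
      ia = ia, ib = ib,
      stats = list(S = S, Q = Q, C = C),
      transform = transform,
      eps = eps
    ),
    class = "reference_network"
  )
}

#' @export
print.reference_network <- function(x, ...) {
  cat("Reference network:", nrow(x$edges), "edges,",
      sum(x$edges$testable), "testable, n =", x$n, "reference samples\n")
  invisible(x)
}

#' Z statistic for a differential correlation
#'
#' `Z = delta / ((1 - pcc_n^2) / (n - 1))`; the divisor is the null
#' standard deviation of the one-sample perturbation `delta` for large `n`.
#' Edges with `|pcc_n| >= 1 - eps` are degenerate and yield `NA`.
#'
#' @param delta differential correlation `PCC_{n+1} - PCC_n` (vectorized).
#' @param pcc_n reference correlation(s).
#' @param n reference sample count (>= 3).
#' @param eps degeneracy guard, default 1e-6.
#' @return Z value(s); `NA` where degenerate.
#' @export
z_statistic <- function(delta, pcc_n, n, eps = 1e-6) {
  if (n < 3) stopf("z_statistic: n must be >= 3")
  out <- delta / ((1 - pcc_n^2) / (n - 1))
  out[is.na(pcc_n) | abs(pcc_n) >= 1 - eps] <- NA_real_
  out
}

#' Two-sided standard-normal p-value for a Z statistic
#'
#' @param z Z value(s); `NA` passes through.
#' @return `2 * (1 - Phi(|z|))`, in \[0, 1\].
#' @export
edge_pvalue <- function(z) {
  2 * stats::pnorm(-abs(z))
}

#' Differential network for one tumor sample
#'
#' Pools the tumor column with the `n` reference samples, recomputes each
#' background edge's correlation `PCC_{n+1}`, and fills `delta`, `z`, `p`
#' and the significance flag. The default `"incremental"` method updates
#' from the cached reference sufficient statistics; `"pooled"` recomputes
#' from the full pooled matrix (requires `expr_ref`). Both agree to
#' round-off and the agreement is part of the test suite.
#'
#' @param ref a `reference_network`.
#' @param tumor_col numeric vector of tumor expression, named by gene (or
#'   aligned with `rownames(expr_ref)` when names are absent).
#' @param sample_id identifier stored with the result.
#' @param expr_ref the reference expression matrix; required for
#'   `method = "pooled"`, unused otherwise.
#' @param alpha_edge per-edge significance level, default 0.01 (strict `<`).
#' @param method `"incremental"` (default) or `"pooled"`.
#' @return data.frame of class `differential_network` with columns
#'   `gene_a`, `gene_b`, `pcc_n`, `pcc_n1`, `delta`, `z`, `p`,
#'   `significant`; attribute `sample_id`.
#' @export
perturb_one_sample <- function(ref, tumor_col, sample_id,
                               expr_ref = NULL, alpha_edge = 0.01,
                               method = c("incremental", "pooled")) {
  method <- match.arg(method)
  x <- align_tumor_col(ref, tumor_col, expr_ref)
  pcc_n1 <- if (method == "incremental") {
    pooled_pcc_incremental(ref, x)
  } else {
    if (is.null(expr_ref)) stopf("method='pooled' requires expr_ref")
    pooled_pcc_full(ref, expr_ref, x)
  }
  delta <- pcc_n1 - ref$edges$pcc_n
  z <- z_statistic(delta, ref$edges$pcc_n, ref$n, ref$eps)
  z[!ref$edges$testable] <- NA_real_
  p <- edge_pvalue(z)
  out <- data.frame(
    gene_a = ref$edges$gene_a,
    gene_b = ref$edges$gene_b,
    pcc_n = ref$edges$pcc_n,
    pcc_n1 = pcc_n1,
    delta = delta,
    z = z,
    p = p,
    significant = !is.na(p) & p < alpha_edge,
    stringsAsFactors = FALSE
  )
  attr(out, "sample_id") <- sample_id
  attr(out, "alpha_edge") <- alpha_edge
  class(out) <- c("differential_network", "data.frame")
  out
}

align_tumor_col <- function(ref, tumor_col, expr_ref = NULL) {
  if (!is.null(names(tumor_col))) {
    miss <- setdiff(ref$genes, names(tumor_col))
    if (length(miss)) stopf("tumor sample lacks %d reference-network genes", length(miss))
    x <- tumor_col[ref$genes]
  } else {
    if (is.null(expr_ref) || is.null(rownames(expr_ref)))
      stopf("unnamed tumor_col requires expr_ref with gene rownames for alignment")
    if (length(tumor_col) != nrow(expr_ref))
      stopf("unnamed tumor_col length differs from nrow(expr_ref)")
    names(tumor_col) <- rownames(expr_ref)
    x <- tumor_col[ref$genes]
  }
  if (!all(is.finite(x))) stopf("non-finite tumor expression values")
  if (ref$transform == "log2p1") x <- log2(x + 1)
  x
}

pooled_pcc_incremental <- function(ref, x) {
  n1 <- ref$n + 1
  S <- ref$stats$S + x
  Q <- ref$stats$Q + x^2
  xa <- x[ref$ia]; xb <- x[ref$ib]
  C <- ref$stats$C + xa * xb
  cov_e <- C - S[ref$ia] * S[ref$ib] / n1
  va <- Q - S^2 / n1
  den <- sqrt(va[ref$ia] * va[ref$ib])
  r <- ifelse(den > 0, cov_e / den, NA_real_)
  pmin(1, pmax(-1, r))
}

pooled_pcc_full <- function(ref, expr_ref, x) {
  if (ref$transform == "log2p1") expr_ref <- log2(expr_ref + 1)
  X <- cbind(expr_ref[ref$genes, , drop = FALSE], x)
  Xc <- X - rowMeans(X)
  ss <- rowSums(Xc^2)
  num <- rowSums(Xc[ref$ia, , drop = FALSE] * Xc[ref$ib, , drop = FALSE])
  den <- sqrt(ss[ref$ia] * ss[ref$ib])
  r <- ifelse(den > 0, num / den, NA_real_)
  pmin(1, pmax(-1, r))
}

#' Differential networks for a whole tumor cohort
#'
#' Applies [perturb_one_sample()] to every column of a tumor expression
#' matrix and collects the per-edge results into edge-by-sample matrices.
#'
#' @param ref a `reference_network`.
#' @param expr_tumor numeric matrix, genes x tumor samples.
#' @param alpha_edge per-edge significance level, default 0.01.
#' @param method correlation update method, see [perturb_one_sample()].
#' @param expr_ref reference expression matrix, required for
#'   `method = "pooled"`.
#' @return object of class `ssn_set`: list with `edges` (data.frame),
#'   `delta`, `z`, `p`, `significant` (edge x sample matrices), `n`,
#'   `alpha_edge`, `sample_ids`.
#' @export
perturb_samples <- function(ref, expr_tumor, alpha_edge = 0.01,
                            method = c("incremental", "pooled"),
                            expr_ref = NULL) {
  method <- match.arg(method)
  if (method == "pooled" && is.null(expr_ref))
    stopf("method='pooled' requires expr_ref")
  if (is.null(rownames(expr_tumor))) stopf("expr_tumor needs gene rownames")
  if (is.null(colnames(expr_tumor))) stopf("expr_tumor needs sample colnames")
  ids <- colnames(expr_tumor)
  ne <- nrow(ref$edges)
  eid <- edge_ids(ref$edges)
  delta <- matrix(NA_real_, ne, length(ids), dimnames = list(eid, ids))
  z <- delta
  for (j in seq_along(ids)) {
    x <- align_tumor_col(ref, expr_tumor[, j], expr_ref)
    pcc_n1 <- if (method == "incremental") pooled_pcc_incremental(ref, x)
              else pooled_pcc_full(ref, expr_ref, x)
    delta[, j] <- pcc_n1 - ref$edges$pcc_n
    zz <- z_statistic(delta[, j], ref$edges$pcc_n, ref$n, ref$eps)
    zz[!ref$edges$testable] <- NA_real_
    z[, j] <- zz
  }
  p <- edge_pvalue(z)
  structure(
    list(edges = ref$edges[, c("gene_a", "gene_b", "pcc_n", "testable")],
         delta = delta, z = z, p = p,
         significant = !is.na(p) & p < alpha_edge,
         n = ref$n, alpha_edge = alpha_edge, sample_ids = ids),
    class = "ssn_set"
  )
}

#' @export
print.ssn_set <- function(x, ...) {
  cat("Sample-specific network set:", nrow(x$delta), "edges x",
      ncol(x$delta), "samples; alpha_edge =", x$alpha_edge, "\n")
  invisible(x)
}

#' Call one sample's specific network
#'
#' The sample-specific network is exactly the set of edges with
#' `p < alpha_edge` (strict).
#'
#' @param diff a `differential_network`.
#' @param alpha_edge significance level in (0,1), default 0.01.
#' @return the significant subset of the edge table.
#' @export
call_sample_network <- function(diff, alpha_edge = 0.01) {
  if (!is.numeric(alpha_edge) || alpha_edge <= 0 || alpha_edge >= 1)
    stopf("alpha_edge must be in (0,1)")
  keep <- !is.na(diff$p) & diff$p < alpha_edge
  out <- diff[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Delta-PCC edge-feature matrix from a set of differential networks
#'
#' Transposes the per-edge delta matrix into the samples x edges layout
#' used by the survival models (each column is one edge biomarker).
#'
#' @param ssn an `ssn_set`.
#' @param testable_only drop untestable edges (default TRUE).
#' @return numeric matrix, samples x edges, edge-id colnames.
#' @export
edge_features <- function(ssn, testable_only = TRUE) {
  d <- ssn$delta
  if (testable_only) d <- d[ssn$edges$testable, , drop = FALSE]
  t(d)
}

#' Write one differential network as TSV
#' @param diff a `differential_network`. @param path output file.
#' @export
write_differential <- function(diff, path) {
  write_tsv_file(as.data.frame(diff), path)
}
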