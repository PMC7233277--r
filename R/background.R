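# Background (template) network: high-confidence interactions restricted to
# pathway genes. All downstream delta-PCC testing runs on this fixed edge
# universe.

#' Load a gene-gene interaction table with confidence scores
#'
#' Reads a headered, tab- or whitespace-separated interaction table, keeps
#' rows whose confidence score is strictly above `score_threshold`,
#' canonicalizes pairs (lexicographically ordered endpoints), drops
#' self-pairs, and collapses duplicate pairs keeping the maximum score.
#' Scores on a 0-1000 scale (the STRING dialect) are rescaled to \[0,1\]
#' when the maximum score exceeds 1; the rescaling is logged.
#'
#' @param path path to the interaction file.
#' @param score_threshold keep rows with `score > score_threshold` (strict);
#'   default 0.9, the conventional high-confidence cutoff.
#' @param columns length-3 character vector naming the two gene columns and
#'   the score column, in that order.
#' @return data.frame of class `interaction_table` with columns `gene_a`,
#'   `gene_b`, `score`.
#' @export
load_interactions <- function(path, score_threshold = 0.9,
                              columns = c("gene_a", "gene_b", "score")) {
  if (!file.exists(path)) stopf("interaction file not found: %s", path)
  if (!is.numeric(score_threshold) || score_threshold < 0 || score_threshold > 1)
    stopf("score_threshold must be in [0,1]")
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          check.names = FALSE)
  missing_cols <- setdiff(columns, names(df))
  if (length(missing_cols))
    stopf("interaction file lacks column(s): %s", paste(missing_cols, collapse = ", "))
  raw_score <- df[[columns[3]]]
  score <- suppressWarnings(as.numeric(raw_score))
  bad <- which(!is.finite(score))
  if (length(bad))
    stopf("non-numeric or non-finite score at data line %d (value '%s')",
          bad[1], as.character(raw_score[bad[1]]))
  if (length(score) && max(score) > 1) {
    ssn_log("scores exceed 1; assuming 0-1000 scale, rescaling to [0,1]")
    score <- score / 1000
  }
  if (any(score < 0 | score > 1))
    stopf("scores outside [0,1] after rescaling")
  tab <- canonicalize_pairs(df[[columns[1]]], df[[columns[2]]])
  tab$score <- score
  tab <- tab[tab$gene_a != tab$gene_b, , drop = FALSE]
  tab <- tab[tab$score > score_threshold, , drop = FALSE]
  if (nrow(tab)) {
    ord <- order(tab$gene_a, tab$gene_b, -tab$score)
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(tab[c("gene_a", "gene_b")]), , drop = FALSE]
  }
  rownames(tab) <- NULL
  class(tab) <- c("interaction_table", "data.frame")
  tab
}

#' Load pathway gene sets in GMT format
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`; the
#' description field is ignored.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (class `gene_set_collection`),
#'   one per pathway; attribute `provenance` records the source path.
#' @export
load_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stopf("GMT parse error at line %d: fewer than 3 tab-separated fields", i)
    nms[i] <- trimws(fields[1])
    genes <- unique(trimws(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes))
      stopf("GMT parse error at line %d: empty gene set '%s'", i, nms[i])
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms))
    stopf("duplicate pathway name in GMT: %s", nms[duplicated(nms)][1])
  names(sets) <- nms
  attr(sets, "provenance") <- path
  class(sets) <- "gene_set_collection"
  sets
}

#' Build the background (template) network
#'
#' Keeps an interaction edge iff both endpoints belong to the pathway gene
#' universe. By default the universe is the union of all pathway gene sets;
#' with `same_pathway = TRUE` both endpoints must share at least one common
#' pathway (the stricter reading).
#'
#' @param interactions an `interaction_table` from [load_interactions()].
#' @param gene_sets a `gene_set_collection` from [load_gmt()].
#' @param same_pathway logical; require a common pathway for the two
#'   endpoints instead of membership in the pooled universe.
#' @return object of class `background_network`: list with `edges`
#'   (data.frame `gene_a`, `gene_b`) and `genes` (character vector of edge
#'   endpoints).
#' @export
build_background <- function(interactions, gene_sets, same_pathway = FALSE) {
  if (!nrow(interactions)) stopf("empty interaction table")
  if (!length(gene_sets)) stopf("empty gene set collection")
  universe <- unique(unlist(unclass(gene_sets), use.names = FALSE))
  keep <- interactions$gene_a %in% universe & interactions$gene_b %in% universe
  if (same_pathway && any(keep)) {
    membership <- lapply(unclass(gene_sets), function(g) g)
    in_common <- function(a, b) {
      any(vapply(membership, function(g) (a %in% g) && (b %in% g), logical(1)))
    }
    idx <- which(keep)
    keep[idx] <- mapply(in_common, interactions$gene_a[idx], interactions$gene_b[idx])
  }
  edges <- interactions[keep, c("gene_a", "gene_b"), drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges))
    warning("background network is empty: no interaction has both endpoints among pathway genes")
  new_background(edges)
}

new_background <- function(edges) {
  edges <- as.data.frame(edges)[, c("gene_a", "gene_b"), drop = FALSE]
  class(edges) <- "data.frame"
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(edges = edges,
         genes = sort(unique(c(edges$gene_a, edges$gene_b)))),
    class = "background_network"
  )
}

#' @export
print.background_network <- function(x, ...) {
  cat("Background network:", nrow(x$edges), "edges over", length(x$genes), "genes\n")
  invisible(x)
}

#' Write a background network as a two-column TSV edge list
#' @param bg a `background_network`. @param path output file.
#' @export
write_background <- function(bg, path) {
  write_tsv_file(bg$edges, path)
}

#' Read a background network from a two-column TSV edge list
#' @param path edge-list file with columns `gene_a`, `gene_b`.
#' @export
read_background <- function(path) {
  df <- read_tsv_file(path)
  edges <- canonicalize_pairs(df$gene_a, df$gene_b)
  edges <- unique(edges[edges$gene_a != edges$gene_b, , drop = FALSE])
  new_background(edges)
}
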