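# Aggregation of per-sample significant edges into disease/stage/subtype
# networks: edge frequencies, exact right-sided binomial test, degree-based
# key genes, and shared/specific gene-set comparisons.

#' Per-edge significance counts within a sample group
#'
#' @param significant logical matrix, edges x samples (e.g. the
#'   `significant` slot of an `ssn_set`).
#' @param members character vector of sample ids forming the group; every
#'   member must be a column of `significant`.
#' @return named integer vector, one count per edge.
#' @export
perturbation_counts <- function(significant, members) {
  if (!length(members)) stopf("empty sample group")
  missing <- setdiff(members, colnames(significant))
  if (length(missing))
    stopf("no differential network for sample(s): %s",
          paste(missing, collapse = ", "))
  counts <- rowSums(significant[, members, drop = FALSE], na.rm = TRUE)
  storage.mode(counts) <- "integer"
  counts
}

#' Exact right-sided binomial test for an edge's perturbation frequency
#'
#' Upper-tail probability `P(X >= count)` for `X ~ Binomial(m, p0)`:
#' does the edge's significance frequency exceed the benchmark proportion
#' `p0`?
#'
#' @param count number of group samples in which the edge is significant
#'   (vectorized).
#' @param m group size.
#' @param p0 null proportion, default 0.9 (the "more than 90% of samples"
#'   benchmark).
#' @return right-tail p-value(s).
#' @export
binomial_edge_test <- function(count, m, p0 = 0.9) {
  if (any(count < 0 | count > m)) stopf("count must lie in [0, m]")
  if (p0 <= 0 || p0 >= 1) stopf("p0 must be in (0,1)")
  stats::pbinom(count - 1, size = m, prob = p0, lower.tail = FALSE)
}

#' Select a group's perturbed edges
#'
#' An edge enters the group-related network iff its significance frequency
#' strictly exceeds `min_frequency` AND the right-sided binomial p-value is
#' strictly below `alpha_group`.
#'
#' @param counts per-edge significance counts (named by edge id).
#' @param m group size.
#' @param p0 binomial null proportion, default 0.9.
#' @param alpha_group binomial significance level, default 0.05.
#' @param min_frequency frequency cut, default 0.9 (strict `>`).
#' @return data.frame with `edge`, `count`, `frequency`, `binom_p`,
#'   `selected`.
#' @export
select_group_edges <- function(counts, m, p0 = 0.9, alpha_group = 0.05,
                               min_frequency = 0.9) {
  frequency <- counts / m
  binom_p <- binomial_edge_test(counts, m, p0)
  data.frame(
    edge = names(counts),
    count = as.integer(counts),
    frequency = frequency,
    binom_p = binom_p,
    selected = frequency > min_frequency & binom_p < alpha_group,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Node degrees of an edge set
#'
#' @param edges data.frame with canonical `gene_a`, `gene_b` columns, or a
#'   character vector of `"a|b"` edge ids.
#' @return named integer vector of degrees (empty for an empty edge set).
#' @export
node_degrees <- function(edges) {
  if (is.character(edges)) edges <- split_edge_ids(edges)
  if (!nrow(edges)) return(stats::setNames(integer(0), character(0)))
  tab <- table(c(edges$gene_a, edges$gene_b))
  stats::setNames(as.integer(tab), names(tab))
}

#' Key genes: nodes with degree strictly above a threshold
#'
#' @param degrees named integer vector from [node_degrees()].
#' @param threshold degree cut, default 5 (strict `>`).
#' @return character vector of gene ids.
#' @export
key_genes <- function(degrees, threshold = 5) {
  sort(names(degrees)[degrees > threshold])
}

#' Shared and group-specific members of named gene sets
#'
#' `shared` is the intersection of all sets; a gene is specific to a group
#' when it belongs to that group's set and to no other.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `shared` (character vector) and `specific` (named list
#'   of character vectors, one per input set).
#' @export
shared_and_specific <- function(sets) {
  if (length(sets) < 2) stopf("need at least 2 named sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stopf("sets must be named")
  shared <- Reduce(intersect, sets)
  specific <- lapply(seq_along(sets), function(i) {
    others <- unique(unlist(sets[-i], use.names = FALSE))
    sort(setdiff(sets[[i]], others))
  })
  names(specific) <- names(sets)
  list(shared = sort(shared), specific = specific)
}

#' Merge raw group labels into analysis groups
#'
#' Applies a label-merging map (e.g. pooling a tiny late stage with the
#' preceding one) to a vector of raw labels. Unmapped labels pass through.
#'
#' @param labels character vector of raw labels.
#' @param merge_map named character vector, `raw label -> analysis group`.
#' @return character vector of analysis-group labels.
#' @export
merge_group_labels <- function(labels, merge_map = character(0)) {
  labels <- as.character(labels)
  hit <- labels %in% names(merge_map)
  labels[hit] <- unname(merge_map[labels[hit]])
  labels
}

#' Group-related network for one sample group
#'
#' Convenience wrapper: counts, binomial test, edge selection, degrees and
#' key genes in one call.
#'
#' @param ssn an `ssn_set`.
#' @param members sample ids of the group.
#' @param name group name.
#' @param p0,alpha_group,min_frequency see [select_group_edges()].
#' @param degree_threshold see [key_genes()], default 5.
#' @return object of class `group_network`: list with `name`, `m`,
#'   `edges` (selection table), `selected` (edge ids), `degrees`,
#'   `key_genes`.
#' @export
group_network <- function(ssn, members, name = "group", p0 = 0.9,
                          alpha_group = 0.05, min_frequency = 0.9,
                          degree_threshold = 5) {
  counts <- perturbation_counts(ssn$significant, members)
  tab <- select_group_edges(counts, length(members), p0, alpha_group,
                            min_frequency)
  selected <- tab$edge[tab$selected]
  degrees <- node_degrees(selected)
  structure(
    list(name = name, m = length(members), edges = tab, selected = selected,
         degrees = degrees, key_genes = key_genes(degrees, degree_threshold)),
    class = "group_network"
  )
}

#' @export
print.group_network <- function(x, ...) {
  cat("Group network '", x$name, "': ", length(x$selected),
      " selected edges of ", nrow(x$edges), " tested (m = ", x$m, "); ",
      length(x$key_genes), " key genes\n", sep = "")
  invisible(x)
}
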