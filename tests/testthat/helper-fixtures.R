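# Fixture builders shared across test files. Everything is generated in
# code; no stored data.

write_interactions_file <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_a = rows$gene_a, gene_b = rows$gene_b,
                   score = rows$score, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_gmt_file <- function(sets, path = tempfile(fileext = ".gmt")) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "desc", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  path
}

# small bivariate-blocks template + reference draw used by several files
tiny_cohort <- function(seed = 42, n_genes = 40, n_edges = 20, n_ref = 50) {
  template <- make_template(n_genes, n_edges, seed = seed)
  reference <- sample_reference(template, n_ref, seed = seed + 1)
  list(template = template, reference = reference,
       ref_net = build_reference(reference, template$background))
}

random_background <- function(genes, n_edges, seed) {
  set.seed(seed)
  pairs <- t(combn(genes, 2))
  pick <- pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
  ed <- canonicalize_pairs(pick[, 1], pick[, 2])
  ssnet:::new_background(ed)
}
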