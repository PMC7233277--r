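#!/usr/bin/env Rscript
# Step 4: hypergeometric pathway enrichment.
#
# Scores the synthetic pathways (template gene blocks) for
# over-representation of the genes incident to the most frequently
# perturbed edges. Pathways with p < 0.05 are called enriched; no
# multiple-testing correction, matching the thresholding convention of
# the rest of the workflow.

suppressPackageStartupMessages(library(ssnet))

data_dir <- "results/data"
bg <- read_background("results/background_edges.tsv")
sets <- load_gmt(file.path(data_dir, "pathways.gmt"))
reference <- read_expression_tsv(file.path(data_dir, "reference_expr.tsv"))
tumors <- read_expression_tsv(file.path(data_dir, "tumor_expr.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "ground_truth.json"),
                             simplifyVector = TRUE)

ref_net <- build_reference(reference, bg)
ssn <- perturb_samples(ref_net, tumors, alpha_edge = 0.01)
freq <- perturbation_counts(ssn$significant, colnames(tumors)) / ncol(tumors)

# key-gene surrogate: genes of the 100 most frequently perturbed edges
top_edges <- names(sort(freq, decreasing = TRUE))[1:100]
keys <- sort(unique(unlist(split_edge_ids(top_edges))))
message(length(keys), " genes incident to the top-100 perturbed edges")

res <- enrich_pathways(keys, sets, bg$genes, alpha = 0.05)
write_tsv_file(res, "results/enrichment_top_perturbed.tsv")
message(sum(res$enriched), " of ", nrow(res), " pathways enriched at p < 0.05")
print(head(res[, c("pathway", "n", "m", "p", "enriched")], 8), row.names = FALSE)

# sanity: blocks hosting planted core edges should rank high
core_genes <- unique(unlist(split_edge_ids(truth$core_edges)))
core_pw <- names(sets)[vapply(sets, function(s) any(core_genes %in% s), logical(1))]
message("pathways containing planted core genes: ",
        paste(core_pw, collapse = ", "))
message("their median enrichment rank: ",
        median(match(core_pw, res$pathway)), " of ", nrow(res))
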