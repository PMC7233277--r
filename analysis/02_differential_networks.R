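#!/usr/bin/env Rscript
# Step 2: background network and per-sample differential networks.
#
# Rebuilds the background from the scored interaction table restricted to
# pathway genes (score > 0.9), computes the reference co-expression
# network over the normal samples, then adds each tumor one at a time and
# tests every edge's delta-PCC with the Z-test (two-sided, alpha 0.01).

suppressPackageStartupMessages(library(ssnet))

data_dir <- "results/data"
inter <- load_interactions(file.path(data_dir, "interactions.tsv"), 0.9)
sets <- load_gmt(file.path(data_dir, "pathways.gmt"))
bg <- build_background(inter, sets)
print(bg)
write_background(bg, "results/background_edges.tsv")

reference <- read_expression_tsv(file.path(data_dir, "reference_expr.tsv"))
tumors <- read_expression_tsv(file.path(data_dir, "tumor_expr.tsv"))
ref_net <- build_reference(reference, bg)
print(ref_net)

ssn <- perturb_samples(ref_net, tumors, alpha_edge = 0.01)
sizes <- colSums(ssn$significant)
write_tsv_file(data.frame(sample_id = ssn$sample_ids, significant_edges = sizes),
               "results/ssn_sizes.tsv")
message(sprintf("sample-specific networks: median %.0f significant edges per tumor (IQR %.0f-%.0f) out of %d tested",
                median(sizes), quantile(sizes, 0.25), quantile(sizes, 0.75),
                sum(ssn$edges$testable)))

one <- perturb_one_sample(ref_net, tumors[, 1], colnames(tumors)[1])
write_differential(one, "results/example_differential_network.tsv")
message("wrote results/ssn_sizes.tsv and an example per-sample network")
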