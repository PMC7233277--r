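# ssnet — sample-specific co-expression perturbation networks and edge-biomarker prognosis

`ssnet` is an R package and analysis workflow for **personalized network
analysis of tumor expression data**. Instead of asking which genes are
differentially expressed in a cohort, it asks which gene–gene
co-expression relationships are *perturbed in each individual sample*,
and then uses those per-sample perturbations as the unit of analysis for
disease networks, key genes, pathway enrichment and survival modeling.

It is aimed at computational biologists working with a tumor expression
matrix, a matched panel of normal reference tissue, an interaction
network with confidence scores (e.g. a STRING-style edge list), pathway
gene sets in GMT format, and per-patient clinical follow-up.

## The model

All testing runs on a fixed **background network**: interactions with
confidence score > 0.9 whose endpoints both belong to the pathway gene
universe. For an edge with Pearson correlation `PCC_n` across the `n`
reference samples, adding one tumor sample and recomputing on the pooled
`n+1` samples gives `PCC_{n+1}` and the perturbation statistic

    ΔPCC = PCC_{n+1} − PCC_n,      Z = ΔPCC / ((1 − PCC_n²)/(n − 1)),

where the denominator is the null standard deviation of `ΔPCC`. Edges
with two-sided normal p < 0.01 form the **sample-specific network**.
Downstream:

* **group networks** — edges significant in >90% of a sample group,
  confirmed by an exact right-tail binomial test (p₀ = 0.9, α = 0.05);
* **key genes** — nodes with degree > 5 in a group network, compared
  across groups as shared/specific sets;
* **pathway enrichment** — hypergeometric upper tail
  `p(m,M,N,n) = 1 − Σ_{i<m} C(M,i)C(N−M,n−i)/C(N,n)` at α = 0.05;
* **prognosis** — univariate Cox screen of ΔPCC edge features
  (p < 0.05), LASSO-Cox selection with seeded 4-fold cross-validation,
  risk score = the fitted linear predictor, median split,
  Kaplan–Meier/log-rank, and transfer of a trained model to an external
  cohort with explicit reporting of omitted edges.

A synthetic-cohort generator with full ground truth (block-factor
Gaussian template, planted covariance perturbations with partially
overlapping stage/subtype edge sets, proportional-hazards survival on
designated edges) backs the test suite and the `analysis/` workflow.

## Worked example

```r
library(ssnet)

cfg <- simulation_config(seed = 1, n_genes = 120, n_edges = 400,
                         n_reference = 150, n_tumors = 120,
                         n_core_edges = 10, n_specific_edges = 4,
                         n_hazard_edges = 2)
cohort <- simulate_cohort(cfg)
#> Simulated cohort: 120 genes; 150 reference and 120 tumor samples; 400 template edges

# one tumor's sample-specific network (top of the edge table)
one <- perturb_one_sample(cohort$ref_net, cohort$tumors[, 1], "tum001")
head(call_sample_network(one), 3)
#>   gene_a gene_b     pcc_n    pcc_n1       delta         z            p significant
#> 1  g0010  g0013 0.4908086 0.4742779 -0.01653073 -3.244707 0.0011757155        TRUE
#> 2  g0050  g0055 0.4188690 0.3979424 -0.02092657 -3.781533 0.0001558654        TRUE
#> 3  g0075  g0076 0.6237471 0.6120232 -0.01172395 -2.859315 0.0042455677        TRUE

# planted edges are perturbed in about twice as many samples as background
freq <- perturbation_counts(cohort$ssn$significant,
                            cohort$labels$sample_id) / ncol(cohort$tumors)
round(c(planted = mean(freq[cohort$truth$core_edges]),
        background = mean(freq[setdiff(names(freq), cohort$truth$core_edges)])), 3)
#>    planted background
#>      0.078      0.032

# hypergeometric enrichment of the genes on the 40 most perturbed edges
keys <- unique(unlist(split_edge_ids(names(sort(freq, decreasing = TRUE))[1:40])))
head(enrich_pathways(keys, template_pathways(cohort$template),
                     cohort$background$genes), 3)
#>               pathway   N  M n m           p enriched
#> 1 SYNTHETIC_BLOCK_013 120 50 8 7 0.008960048     TRUE
#> 2 SYNTHETIC_BLOCK_007 120 50 8 6 0.054631570    FALSE
#> 3 SYNTHETIC_BLOCK_009 120 50 8 6 0.054631570    FALSE

# edge-biomarker survival model: screen, LASSO-Cox, median-split log-rank
screen <- univariate_cox_screen(cohort$features, cohort$survival)
model  <- lasso_cox_select(cohort$features[, screen$edge[screen$keep]],
                           cohort$survival, folds = 4, seed = 1)
model
#> Risk model: 21 edge biomarkers (lambda = 0.09321 , 4 fold CV, seed 1 )
names(cohort$truth$hazard_coefs) %in% model$edges   # both planted edges recovered
#> [1] TRUE TRUE
km_logrank(cohort$survival,
           median_split(risk_score(model, cohort$features)))$logrank_p
#> [1] 8.447511e-13
```

The reading: the enrichment table's first row says 7 of the 8
background genes of block 13 are among the 50 top-perturbed genes
(p ≈ 0.009); the survival model recovers both planted hazard edges and
separates high- from low-risk patients at log-rank p ≈ 8×10⁻¹³.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/05_prognosis.R` run the study
end-to-end at desk scale (300 genes, 2,000 edges, 200 reference + 200
tumor samples across 4 stages × 4 subtypes), writing all tables under
`results/`. Each script is a thin narrative driver over the package
functions; `run_full_pipeline()` performs the same chain as a single
call with a manifest (seed, versions, input hashes, per-stage counts).

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

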