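test_that("make_template handles the empty network and produces valid covariances", {
  t0 <- make_template(10, 0, seed = 601)
  expect_equal(nrow(t0$background$edges), 0L)
  expect_equal(t0$sigma, diag(10), ignore_attr = TRUE)

  tpl <- make_template(60, 100, seed = 602)
  expect_equal(nrow(tpl$background$edges), 100L)
  # positive definite and consistent with recorded per-edge targets
  ev <- eigen(tpl$sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  rho <- tpl$edge_rho
  expect_true(all(abs(rho) >= 0.3 - 1e-12 & abs(rho) <= 0.8 + 1e-12))
  i <- match(tpl$background$edges$gene_a, tpl$genes)
  j <- match(tpl$background$edges$gene_b, tpl$genes)
  expect_equal(unname(rho), tpl$sigma[cbind(i, j)])
  expect_error(make_template(4, 10, seed = 1), "exceeds")
  expect_error(make_template(4, 2), "seed")
})

test_that("two disjoint pairs at rho 0.5 give the closed-form block covariance", {
  tpl <- make_template(4, 2, seed = 603, rho_range = c(0.5, 0.5),
                       prob_negative = 0)
  expect_equal(sort(unname(tpl$edge_rho)), c(0.5, 0.5))
  expect_equal(sort(unique(as.vector(tpl$sigma))), c(0, 0.5, 1))
})

test_that("generators are pure functions of their seed", {
  a <- make_template(30, 40, seed = 604)
  b <- make_template(30, 40, seed = 604)
  expect_identical(a, b)
  expect_false(identical(a, make_template(30, 40, seed = 605)))
  ra <- sample_reference(a, 25, seed = 7)
  rb <- sample_reference(a, 25, seed = 7)
  expect_identical(ra, rb)
})

test_that("reference draws match the template statistics at large n", {
  tpl <- make_template(40, 20, seed = 606)
  expr <- sample_reference(tpl, 1000, seed = 607)
  expect_equal(dim(expr), c(40L, 1000L))
  expect_lt(max(abs(rowMeans(expr))), 0.15)
  ed <- tpl$background$edges
  for (k in sample(nrow(ed), 8)) {
    r <- cor(expr[ed$gene_a[k], ], expr[ed$gene_b[k], ])
    expect_equal(r, unname(tpl$edge_rho[k]), tolerance = 0.12)
  }
})

test_that("the positive expression scale stays positive and preserves rank structure", {
  tpl <- make_template(20, 10, seed = 608)
  expr <- sample_reference(tpl, 200, seed = 609, scale = "positive")
  expect_true(all(expr > 0))
  g <- tpl$background$edges[1, ]
  r_pos <- cor(expr[g$gene_a, ], expr[g$gene_b, ], method = "spearman")
  expect_equal(sign(r_pos), sign(tpl$edge_rho[1]), ignore_attr = TRUE)
})

test_that("strength 0 tumors are draws from the reference distribution", {
  tpl <- make_template(30, 15, seed = 610)
  tum <- sample_tumors(tpl, list(null = list(n = 400, edges = names(tpl$edge_rho)[1:3],
                                             strength = 0)), seed = 611)
  expect_equal(tum$truth$null$rho_after, tum$truth$null$rho_before)
  ed <- tpl$background$edges[1, ]
  r <- cor(tum$expr[ed$gene_a, ], tum$expr[ed$gene_b, ])
  expect_equal(r, unname(tpl$edge_rho[1]), tolerance = 0.15)
})

test_that("a planted inversion flips the realized co-expression and the mean delta-PCC", {
  tpl <- make_template(40, 20, seed = 612, prob_negative = 0)
  target <- names(which.max(tpl$edge_rho))
  shift <- -2 * max(tpl$edge_rho)
  tum <- sample_tumors(tpl, list(g = list(n = 300, edges = target,
                                          strength = shift)), seed = 613)
  ed <- split_edge_ids(target)
  r_new <- cor(tum$expr[ed$gene_a, ], tum$expr[ed$gene_b, ])
  expect_lt(r_new, 0)

  reference <- sample_reference(tpl, 200, seed = 614)
  ref_net <- build_reference(reference, tpl$background)
  ssn <- perturb_samples(ref_net, tum$expr)
  expect_lt(mean(ssn$delta[target, ]), 0)
  # the planted edge shows the strongest average perturbation
  expect_equal(names(which.max(abs(rowMeans(ssn$delta)))), target)
})

test_that("positive definiteness is restored by shrinking with a warning", {
  tpl <- make_template(12, 12, seed = 615, rho_range = c(0.75, 0.8),
                       prob_negative = 0)
  # push every edge of one dense block far negative: infeasible jointly
  blk <- names(tpl$blocks)[tpl$blocks == 1]
  eids <- names(tpl$edge_rho)[split_edge_ids(names(tpl$edge_rho))$gene_a %in% blk]
  expect_warning(
    tum <- sample_tumors(tpl, list(g = list(n = 5, edges = eids, strength = -1.7)),
                         seed = 616),
    "positive definite")
  expect_true(all(is.finite(tum$expr)))
})

test_that("sample_survival honors censoring and links hazard to features", {
  set.seed(617)
  X <- matrix(rnorm(400), 200, 2,
              dimnames = list(paste0("s", 1:200), c("e1", "e2")))
  s0 <- sample_survival(X, setNames(numeric(0), character(0)),
                        censoring_rate = 0, seed = 618)
  expect_true(all(s0$event == 1))
  s1 <- sample_survival(X, c(e1 = 2), censoring_rate = 0, seed = 619)
  hi <- s1$time[X[, "e1"] > 0]
  lo <- s1$time[X[, "e1"] <= 0]
  expect_lt(median(hi), median(lo))
  s2 <- sample_survival(X, c(e1 = 0), censoring_rate = 0.4, seed = 620)
  expect_gt(mean(s2$event == 0), 0.25)
  expect_lt(mean(s2$event == 0), 0.55)
  expect_error(sample_survival(X, c(zz = 1), seed = 1), "missing from features")
})

test_that("simulate_cohort assembles consistent dimensions and ground truth", {
  cfg <- simulation_config(seed = 621, n_genes = 60, n_edges = 90,
                           n_reference = 50, n_tumors = 48,
                           n_core_edges = 6, n_specific_edges = 2,
                           n_hazard_edges = 2)
  co <- suppressWarnings(simulate_cohort(cfg))
  expect_equal(ncol(co$tumors), 48L)
  expect_equal(nrow(co$features), 48L)
  expect_setequal(co$labels$sample_id, co$survival$sample_id)
  expect_setequal(unique(co$labels$stage), cfg$stage_names)
  expect_setequal(unique(co$labels$subtype), cfg$subtype_names)
  # planted overlap structure: every stage set contains the core
  for (s in cfg$stage_names)
    expect_true(all(co$truth$core_edges %in% co$truth$stage_planted[[s]]))
  sp <- shared_and_specific(co$truth$stage_planted)
  expect_setequal(sp$shared, co$truth$core_edges)
  expect_equal(unname(lengths(sp$specific)), rep(2L, 4))
  expect_true(all(names(co$truth$hazard_coefs) %in% colnames(co$features)))
})

test_that("write_cohort emits a complete, reloadable plain-text bundle", {
  cfg <- simulation_config(seed = 622, n_genes = 40, n_edges = 40,
                           n_reference = 30, n_tumors = 32,
                           n_core_edges = 4, n_specific_edges = 1,
                           n_hazard_edges = 2)
  co <- suppressWarnings(simulate_cohort(cfg))
  dir <- file.path(tempdir(), "cohort_out")
  write_cohort(co, dir)
  files <- c("reference_expr.tsv", "tumor_expr.tsv", "template_edges.tsv",
             "clinical.tsv", "pathways.gmt", "interactions.tsv",
             "ground_truth.json")
  expect_true(all(file.exists(file.path(dir, files))))
  expect_equal(read_expression_tsv(file.path(dir, "reference_expr.tsv")),
               co$reference)
  # the scored interaction table reconstructs exactly the template edges
  inter <- load_interactions(file.path(dir, "interactions.tsv"), 0.9)
  sets <- load_gmt(file.path(dir, "pathways.gmt"))
  bg <- build_background(inter, sets)
  expect_equal(bg$edges, co$background$edges)
})
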