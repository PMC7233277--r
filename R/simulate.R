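# Synthetic cohorts with known ground truth. Reference samples are drawn
# from a block-factor Gaussian (one latent factor per gene block), which
# gives a positive-definite covariance by construction and per-edge target
# correlations in a stated range. Tumor groups are drawn from covariances
# in which the group's planted edges have their correlation shifted by a
# stated strength. Survival times follow a proportional-hazards model
# whose linear predictor is a weighted sum of delta-PCC edge features.

#' Random template network with a valid correlation structure
#'
#' Genes are partitioned into blocks; within a block, gene g loads on the
#' block factor with loading `sqrt(a_g)` and random sign, so the pair
#' correlation is `s_i s_j sqrt(a_i a_j)` with magnitude inside
#' `rho_range`. Template edges are sampled among within-block pairs; the
#' joint covariance is positive definite by construction.
#'
#' @param n_genes number of genes.
#' @param n_edges number of template edges (`<= n_genes(n_genes-1)/2`).
#' @param seed RNG seed (mandatory).
#' @param rho_range magnitude range for target correlations, default
#'   c(0.3, 0.8).
#' @param prob_negative probability a gene's factor loading is negative,
#'   default 0.3.
#' @return object of class `ssn_template`: list with `background`
#'   (a `background_network`), `sigma` (gene correlation matrix), `genes`,
#'   `edge_rho` (named target correlation per edge), `blocks`.
#' @export
make_template <- function(n_genes, n_edges, seed, rho_range = c(0.3, 0.8),
                          prob_negative = 0.3) {
  if (missing(seed)) stopf("seed is mandatory")
  if (n_edges > n_genes * (n_genes - 1) / 2)
    stopf("n_edges exceeds the number of available gene pairs")
  set.seed(seed)
  width <- max(4, nchar(as.character(n_genes)))
  genes <- sprintf(paste0("g%0", width, "d"), seq_len(n_genes))

  if (n_edges == 0) {
    bg <- new_background(data.frame(gene_a = character(0), gene_b = character(0),
                                    stringsAsFactors = FALSE))
    sigma <- diag(n_genes)
    dimnames(sigma) <- list(genes, genes)
    return(structure(list(background = bg, sigma = sigma, genes = genes,
                          edge_rho = stats::setNames(numeric(0), character(0)),
                          blocks = stats::setNames(seq_len(n_genes), genes)),
                     class = "ssn_template"))
  }

  # smallest block size whose equal-block capacity covers n_edges
  b <- 2
  while (b < n_genes && (n_genes %/% b) * choose(b, 2) < n_edges) b <- b + 1
  blocks <- stats::setNames(((seq_len(n_genes) - 1) %/% b) + 1, genes)

  a <- stats::runif(n_genes, rho_range[1], rho_range[2])
  s <- sample(c(1, -1), n_genes, replace = TRUE,
              prob = c(1 - prob_negative, prob_negative))
  load <- s * sqrt(a)
  sigma <- diag(n_genes)
  for (blk in unique(blocks)) {
    idx <- which(blocks == blk)
    if (length(idx) < 2) next
    sub <- outer(load[idx], load[idx])
    diag(sub) <- 1
    sigma[idx, idx] <- sub
  }
  dimnames(sigma) <- list(genes, genes)
  stopifnot(all(is.finite(suppressWarnings(chol(sigma)))))  # PD by construction

  pairs <- do.call(rbind, lapply(unique(blocks), function(blk) {
    idx <- which(blocks == blk)
    if (length(idx) < 2) return(NULL)
    cmb <- utils::combn(idx, 2)
    data.frame(i = cmb[1, ], j = cmb[2, ])
  }))
  if (nrow(pairs) < n_edges)
    stopf("internal: block capacity %d < n_edges %d", nrow(pairs), n_edges)
  pick <- pairs[sample(nrow(pairs), n_edges), , drop = FALSE]
  edges <- data.frame(gene_a = genes[pick$i], gene_b = genes[pick$j],
                      stringsAsFactors = FALSE)  # i < j, names share order
  bg <- new_background(edges)
  eid <- edge_ids(bg$edges)
  rho <- sigma[cbind(match(bg$edges$gene_a, genes), match(bg$edges$gene_b, genes))]
  structure(list(background = bg, sigma = sigma, genes = genes,
                 edge_rho = stats::setNames(rho, eid), blocks = blocks),
            class = "ssn_template")
}

#' @export
print.ssn_template <- function(x, ...) {
  cat("Simulation template:", length(x$genes), "genes,",
      nrow(x$background$edges), "edges,", length(unique(x$blocks)), "blocks\n")
  invisible(x)
}

expr_matrix_from_draws <- function(draws, genes, prefix, scale, location) {
  mat <- t(draws)
  if (scale == "positive") mat <- 2^(mat + location)
  rownames(mat) <- genes
  colnames(mat) <- sprintf("%s%03d", prefix, seq_len(ncol(mat)))
  mat
}

#' Draw reference (normal) samples from the template distribution
#'
#' @param template an `ssn_template`.
#' @param n_reference number of samples.
#' @param seed RNG seed.
#' @param scale `"gaussian"` (default) or `"positive"`
#'   (`2^(x + location)`, a TPM-like strictly positive scale).
#' @param location log2 location for the positive scale, default 4.
#' @return numeric matrix, genes x samples.
#' @export
sample_reference <- function(template, n_reference, seed,
                             scale = c("gaussian", "positive"), location = 4) {
  scale <- match.arg(scale)
  set.seed(seed)
  draws <- rmvnorm_chol(n_reference, template$sigma)
  expr_matrix_from_draws(draws, template$genes, "ref", scale, location)
}

perturbed_sigma <- function(template, edge_set, strength) {
  sigma <- template$sigma
  ed <- split_edge_ids(edge_set)
  i <- match(ed$gene_a, template$genes)
  j <- match(ed$gene_b, template$genes)
  if (anyNA(i) || anyNA(j)) stopf("planted edge outside the template gene set")
  old <- sigma[cbind(i, j)]
  target <- pmin(0.99, pmax(-0.99, old + rep_len(strength, length(old))))
  delta <- target - old
  shrink <- 1
  repeat {
    cand <- sigma
    cand[cbind(i, j)] <- old + shrink * delta
    cand[cbind(j, i)] <- old + shrink * delta
    ok <- !inherits(try(chol(cand), silent = TRUE), "try-error")
    if (ok) {
      if (shrink < 1)
        warning(sprintf("perturbation strength reduced by factor %.2f to keep the covariance positive definite", shrink))
      return(list(sigma = cand, rho_before = old, rho_after = old + shrink * delta))
    }
    shrink <- shrink * 0.9
    if (shrink < 1e-3) stopf("could not restore positive definiteness")
  }
}

#' Draw tumor samples with planted co-expression perturbations
#'
#' Each group is drawn from a covariance in which the group's planted
#' edges have their correlation shifted by the group's strength (clamped
#' to (-0.99, 0.99)); other entries are unchanged. If the perturbed matrix
#' loses positive definiteness the shift is shrunk with a warning.
#'
#' @param template an `ssn_template`.
#' @param groups named list; each element is a list with `n` (samples),
#'   `edges` (character vector of planted edge ids, subset of template
#'   edges) and `strength` (correlation shift, scalar or per-edge).
#' @param seed RNG seed.
#' @param scale,location see [sample_reference()].
#' @return list with `expr` (genes x samples), `labels` (data.frame
#'   `sample_id`, `group`) and `truth` (per-group planted edges and
#'   realized correlation shifts).
#' @export
sample_tumors <- function(template, groups, seed,
                          scale = c("gaussian", "positive"), location = 4) {
  scale <- match.arg(scale)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stopf("groups must be named")
  set.seed(seed)
  mats <- list(); labs <- list(); truth <- list()
  counter <- 0
  for (g in names(groups)) {
    spec <- groups[[g]]
    if (length(spec$edges)) {
      pert <- perturbed_sigma(template, spec$edges, spec$strength)
      sig <- pert$sigma
      truth[[g]] <- list(edges = spec$edges,
                         strength = spec$strength,
                         rho_before = pert$rho_before,
                         rho_after = pert$rho_after)
    } else {
      sig <- template$sigma
      truth[[g]] <- list(edges = character(0), strength = 0,
                         rho_before = numeric(0), rho_after = numeric(0))
    }
    draws <- rmvnorm_chol(spec$n, sig)
    mat <- t(draws)
    if (scale == "positive") mat <- 2^(mat + location)
    rownames(mat) <- template$genes
    colnames(mat) <- sprintf("tum%03d", counter + seq_len(spec$n))
    counter <- counter + spec$n
    mats[[g]] <- mat
    labs[[g]] <- data.frame(sample_id = colnames(mat), group = g,
                            stringsAsFactors = FALSE)
  }
  list(expr = do.call(cbind, mats),
       labels = do.call(rbind, c(labs, list(make.row.names = FALSE))),
       truth = truth)
}

#' Survival times from a proportional-hazards model on edge features
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(sum coef_e * feature_e)`; censoring times are an
#' independent exponential whose rate gives the stated expected censoring
#' fraction under the baseline hazard.
#'
#' @param features samples x edges delta-PCC matrix.
#' @param true_coefs named numeric vector of hazard coefficients; names
#'   must be feature columns.
#' @param baseline_rate baseline hazard (events per day), default 1e-3.
#' @param censoring_rate expected censored fraction in \[0, 1); 0 means no
#'   censoring. Default 0.3.
#' @param seed RNG seed.
#' @return data.frame with `sample_id`, `time`, `event`.
#' @export
sample_survival <- function(features, true_coefs, baseline_rate = 1e-3,
                            censoring_rate = 0.3, seed) {
  if (missing(seed)) stopf("seed is mandatory")
  miss <- setdiff(names(true_coefs), colnames(features))
  if (length(miss)) stopf("hazard coefficient edges missing from features: %s",
                          paste(miss, collapse = ", "))
  if (censoring_rate < 0 || censoring_rate >= 1)
    stopf("censoring_rate must be in [0, 1)")
  set.seed(seed)
  n <- nrow(features)
  lp <- if (length(true_coefs))
    drop(features[, names(true_coefs), drop = FALSE] %*% true_coefs)
  else rep(0, n)
  hazard <- baseline_rate * exp(lp)
  t_event <- stats::rexp(n) / hazard
  if (censoring_rate == 0) {
    time <- t_event
    event <- rep(1L, n)
  } else {
    cens_rate <- baseline_rate * censoring_rate / (1 - censoring_rate)
    t_cens <- stats::rexp(n, rate = cens_rate)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  }
  data.frame(sample_id = rownames(features), time = time, event = event,
             stringsAsFactors = FALSE)
}

#' Synthetic-pathway gene sets from the template blocks
#'
#' Each gene block becomes one "pathway", giving a gene-set collection
#' whose union covers the whole template.
#'
#' @param template an `ssn_template`.
#' @return a `gene_set_collection`.
#' @export
template_pathways <- function(template) {
  sets <- split(names(template$blocks), template$blocks)
  names(sets) <- sprintf("SYNTHETIC_BLOCK_%03d", as.integer(names(sets)))
  attr(sets, "provenance") <- "synthetic template blocks"
  class(sets) <- "gene_set_collection"
  sets
}

#' Write a gene-set collection as a GMT file
#' @param sets a `gene_set_collection`. @param path output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Default simulation configuration
#'
#' Desk-scale cohort defaults: 300 genes, 2,000 template edges, 200
#' reference samples, 200 tumors, 4 stages x 4 subtypes. Planted edges are
#' drawn among strong positive-correlation edges (rho >= 0.4): a shared
#' disease core perturbed in every group plus stage- and subtype-specific
#' sets, all shifted by `strength` (default -1.0, a strong loss/inversion
#' of co-expression). Three core edges additionally drive survival with a
#' hazard ratio `hr_per_sd` per standard deviation of their delta-PCC.
#'
#' @param seed RNG seed (mandatory).
#' @param ... overrides for any default field.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed, ...) {
  if (missing(seed)) stopf("seed is mandatory")
  cfg <- list(
    n_genes = 300, n_edges = 2000, n_reference = 200, n_tumors = 200,
    stage_names = c("StageI", "StageII", "StageIII", "StageIV"),
    subtype_names = c("LuminalA", "LuminalB", "HER2", "Basal"),
    n_core_edges = 20, n_specific_edges = 10,
    strength = -1.0, min_planted_rho = 0.4,
    n_hazard_edges = 3, hr_per_sd = 2.5,
    baseline_hazard = 1e-3, censoring_rate = 0.3,
    rho_range = c(0.3, 0.8), prob_negative = 0.3,
    alpha_edge = 0.01, scale = "gaussian", seed = seed
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a full cohort with ground truth
#'
#' Generates the template network and its correlated reference population,
#' tumor samples whose stage and subtype groups carry partially overlapping
#' planted-edge perturbations (a shared disease core plus group-specific
#' sets), computes the differential networks and delta-PCC features, and
#' draws survival from a proportional-hazards model on designated core
#' edges. All randomness derives from `config$seed`.
#'
#' @param config a `simulation_config`.
#' @return object of class `simulated_cohort`: list with `template`,
#'   `background`, `reference`, `tumors`, `labels` (sample_id, stage,
#'   subtype), `survival`, `ref_net`, `ssn`, `features`, `truth`
#'   (planted-edge sets per group, hazard coefficients, config).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cfg <- config
  template <- make_template(cfg$n_genes, cfg$n_edges, seed = cfg$seed,
                            rho_range = cfg$rho_range,
                            prob_negative = cfg$prob_negative)
  reference <- sample_reference(template, cfg$n_reference, seed = cfg$seed + 1,
                                scale = cfg$scale)

  # planted-edge design: shared core + stage-specific + subtype-specific,
  # drawn among strong positive edges so the shift is a loss/inversion
  set.seed(cfg$seed + 2)
  eid <- names(template$edge_rho)
  eligible <- eid[template$edge_rho >= cfg$min_planted_rho]
  need <- cfg$n_core_edges +
    cfg$n_specific_edges * (length(cfg$stage_names) + length(cfg$subtype_names))
  if (length(eligible) < need) {
    ssn_log("only %d edges with rho >= %.2f; drawing remainder from strongest |rho|",
            length(eligible), cfg$min_planted_rho)
    eligible <- eid[order(-abs(template$edge_rho))][seq_len(min(need, length(eid)))]
  }
  picked <- sample(eligible, need)
  core <- picked[seq_len(cfg$n_core_edges)]
  rest <- picked[-seq_len(cfg$n_core_edges)]
  stage_specific <- split(rest[seq_len(cfg$n_specific_edges * length(cfg$stage_names))],
                          rep(cfg$stage_names, each = cfg$n_specific_edges))
  rest2 <- rest[-seq_len(cfg$n_specific_edges * length(cfg$stage_names))]
  subtype_specific <- split(rest2, rep(cfg$subtype_names, each = cfg$n_specific_edges))

  # stage x subtype combination groups; each combination's covariance
  # carries the union of the core and both specific sets
  combos <- expand.grid(stage = cfg$stage_names, subtype = cfg$subtype_names,
                        stringsAsFactors = FALSE)
  n_per <- diff(round(seq(0, cfg$n_tumors, length.out = nrow(combos) + 1)))
  groups <- list()
  for (k in seq_len(nrow(combos))) {
    nm <- paste(combos$stage[k], combos$subtype[k], sep = ".")
    groups[[nm]] <- list(
      n = n_per[k],
      edges = unique(c(core, stage_specific[[combos$stage[k]]],
                       subtype_specific[[combos$subtype[k]]])),
      strength = cfg$strength
    )
  }
  tum <- sample_tumors(template, groups, seed = cfg$seed + 3, scale = cfg$scale)
  parts <- strsplit(tum$labels$group, ".", fixed = TRUE)
  labels <- data.frame(
    sample_id = tum$labels$sample_id,
    stage = vapply(parts, `[`, character(1), 1L),
    subtype = vapply(parts, `[`, character(1), 2L),
    stringsAsFactors = FALSE
  )

  ref_net <- build_reference(reference, template$background)
  ssn <- perturb_samples(ref_net, tum$expr, alpha_edge = cfg$alpha_edge)
  features <- edge_features(ssn)

  set.seed(cfg$seed + 4)
  hazard_edges <- sample(intersect(core, colnames(features)), cfg$n_hazard_edges)
  signs <- rep_len(c(1, -1), cfg$n_hazard_edges)
  sds <- apply(features[, hazard_edges, drop = FALSE], 2, stats::sd)
  coefs <- stats::setNames(signs * log(cfg$hr_per_sd) / sds, hazard_edges)
  survival <- sample_survival(features, coefs,
                              baseline_rate = cfg$baseline_hazard,
                              censoring_rate = cfg$censoring_rate,
                              seed = cfg$seed + 5)

  structure(
    list(template = template, background = template$background,
         reference = reference, tumors = tum$expr, labels = labels,
         survival = survival, ref_net = ref_net, ssn = ssn,
         features = features,
         truth = list(core_edges = core,
                      stage_specific = stage_specific,
                      subtype_specific = subtype_specific,
                      stage_planted = lapply(stats::setNames(cfg$stage_names, cfg$stage_names),
                                             function(s) unique(c(core, stage_specific[[s]]))),
                      subtype_planted = lapply(stats::setNames(cfg$subtype_names, cfg$subtype_names),
                                               function(s) unique(c(core, subtype_specific[[s]]))),
                      combo_truth = tum$truth,
                      hazard_coefs = as.list(coefs),  # list keeps names in JSON
                      config = unclass(cfg))),
    class = "simulated_cohort"
  )
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$reference), "genes;",
      ncol(x$reference), "reference and", ncol(x$tumors), "tumor samples;",
      nrow(x$ssn$delta), "template edges\n")
  invisible(x)
}

#' Write a simulated cohort to plain-text files
#'
#' Writes reference and tumor expression TSVs, the template edge list, a
#' clinical table (`sample_id`, `time`, `event`, `stage`, `subtype`), a
#' synthetic-pathway GMT, an interaction table with confidence scores
#' (template edges scored above 0.9 plus low-scored decoy pairs), and the
#' ground-truth JSON.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_tsv(cohort$reference, file.path(dir, "reference_expr.tsv"))
  write_expression_tsv(cohort$tumors, file.path(dir, "tumor_expr.tsv"))
  write_background(cohort$background, file.path(dir, "template_edges.tsv"))
  clinical <- merge(cohort$survival, cohort$labels, by = "sample_id", sort = FALSE)
  write_tsv_file(clinical, file.path(dir, "clinical.tsv"))
  write_gmt(template_pathways(cohort$template), file.path(dir, "pathways.gmt"))

  # interaction table: template edges score in (0.9, 1]; decoys below 0.9
  set.seed(cohort$truth$config$seed + 6)
  edges <- cohort$background$edges
  n_decoy <- min(500, nrow(edges))
  genes <- cohort$template$genes
  decoy <- canonicalize_pairs(sample(genes, n_decoy, replace = TRUE),
                              sample(genes, n_decoy, replace = TRUE))
  decoy <- decoy[decoy$gene_a != decoy$gene_b, , drop = FALSE]
  inter <- rbind(
    data.frame(edges, score = stats::runif(nrow(edges), 0.905, 0.999)),
    data.frame(decoy, score = stats::runif(nrow(decoy), 0.05, 0.85))
  )
  write_tsv_file(inter, file.path(dir, "interactions.tsv"))

  jsonlite::write_json(cohort$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
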