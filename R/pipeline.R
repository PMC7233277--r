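# End-to-end orchestration: simulate (or load) -> background -> per-sample
# differential networks -> group networks (all / stage / subtype) ->
# pathway enrichment -> edge-biomarker prognosis. All intermediates are
# plain TSV/JSON; a manifest records seed, versions, input hashes and
# per-stage counts.

#' Pipeline configuration
#'
#' @param out_dir run directory (created).
#' @param seed RNG seed (mandatory).
#' @param simulate logical; generate inputs with [simulate_cohort()]
#'   (TRUE, default) or read them from `inputs` paths.
#' @param inputs named list of paths (`reference`, `tumors`,
#'   `interactions`, `gmt`, `clinical`) when `simulate = FALSE`.
#' @param sim_config a `simulation_config` (defaults to
#'   `simulation_config(seed)`).
#' @param score_threshold interaction confidence cut, default 0.9.
#' @param alpha_edge per-edge significance level, default 0.01.
#' @param min_frequency group frequency cut, default 0.9.
#' @param alpha_group binomial level, default 0.05.
#' @param degree_threshold key-gene degree cut, default 5.
#' @param alpha_enrich enrichment level, default 0.05.
#' @param alpha_screen univariate Cox level, default 0.05.
#' @param cv_folds LASSO-Cox folds, default 4.
#' @param merge_map named character vector merging raw stage labels.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, simulate = TRUE, inputs = list(),
                            sim_config = NULL, score_threshold = 0.9,
                            alpha_edge = 0.01, min_frequency = 0.9,
                            alpha_group = 0.05, degree_threshold = 5,
                            alpha_enrich = 0.05, alpha_screen = 0.05,
                            cv_folds = 4, merge_map = character(0)) {
  if (missing(seed)) stopf("seed is mandatory")
  stopifnot(score_threshold >= 0, score_threshold <= 1,
            alpha_edge > 0, alpha_edge < 1, min_frequency > 0,
            min_frequency < 1, alpha_group > 0, alpha_group < 1,
            degree_threshold >= 0, alpha_enrich > 0, alpha_enrich < 1,
            alpha_screen > 0, alpha_screen < 1, cv_folds >= 2)
  if (is.null(sim_config) && simulate) sim_config <- simulation_config(seed)
  structure(as.list(environment()), class = "pipeline_config")
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> build-background -> build-ssn ->
#' group-networks (all, stage, subtype) -> enrich -> prognosis, writing
#' every intermediate under `config$out_dir` together with a resolved
#' config snapshot and a machine-readable manifest.
#'
#' @param config a `pipeline_config`.
#' @return the run directory, invisibly; the manifest is
#'   `<out_dir>/manifest.json`.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  data_dir <- file.path(cfg$out_dir, "data")
  counts <- list()

  # stage 1: inputs
  run_stage("simulate", {
    if (cfg$simulate) {
      cohort <- simulate_cohort(cfg$sim_config)
      write_cohort(cohort, data_dir)
    } else {
      needed <- c("reference", "tumors", "interactions", "gmt", "clinical")
      miss <- setdiff(needed, names(cfg$inputs))
      if (length(miss)) stopf("missing input path(s): %s", paste(miss, collapse = ", "))
      dir.create(data_dir, showWarnings = FALSE)
      file.copy(unlist(cfg$inputs[needed]), file.path(data_dir, c(
        "reference_expr.tsv", "tumor_expr.tsv", "interactions.tsv",
        "pathways.gmt", "clinical.tsv")), overwrite = TRUE)
    }
  })
  reference <- read_expression_tsv(file.path(data_dir, "reference_expr.tsv"))
  tumors <- read_expression_tsv(file.path(data_dir, "tumor_expr.tsv"))
  clinical <- read_tsv_file(file.path(data_dir, "clinical.tsv"))
  counts$reference_samples <- ncol(reference)
  counts$tumor_samples <- ncol(tumors)

  # stage 2: background network
  bg <- run_stage("build-background", {
    inter <- load_interactions(file.path(data_dir, "interactions.tsv"),
                               cfg$score_threshold)
    sets <- load_gmt(file.path(data_dir, "pathways.gmt"))
    b <- build_background(inter, sets)
    write_background(b, file.path(cfg$out_dir, "background_edges.tsv"))
    b
  })
  counts$background_edges <- nrow(bg$edges)
  counts$background_genes <- length(bg$genes)

  # stage 3: per-sample differential networks
  ssn <- run_stage("build-ssn", {
    ref_net <- build_reference(reference, bg)
    s <- perturb_samples(ref_net, tumors, alpha_edge = cfg$alpha_edge)
    sig_counts <- colSums(s$significant)
    write_tsv_file(data.frame(sample_id = s$sample_ids,
                              significant_edges = sig_counts),
                   file.path(cfg$out_dir, "ssn_sizes.tsv"))
    s
  })
  counts$testable_edges <- sum(ssn$edges$testable)
  counts$mean_ssn_size <- mean(colSums(ssn$significant))

  # stage 4: group networks
  nets <- run_stage("group-networks", {
    clinical$stage <- merge_group_labels(clinical$stage, cfg$merge_map)
    groupings <- list(
      all = list(all = clinical$sample_id),
      stage = split(clinical$sample_id, clinical$stage),
      subtype = split(clinical$sample_id, clinical$subtype)
    )
    nets <- list()
    for (axis in names(groupings)) {
      for (g in names(groupings[[axis]])) {
        gn <- group_network(ssn, groupings[[axis]][[g]], name = g,
                            alpha_group = cfg$alpha_group,
                            min_frequency = cfg$min_frequency,
                            degree_threshold = cfg$degree_threshold)
        write_tsv_file(gn$edges,
                       file.path(cfg$out_dir, sprintf("group_%s_%s.tsv", axis, g)))
        nets[[axis]][[g]] <- gn
      }
    }
    for (axis in c("stage", "subtype")) {
      kg <- lapply(nets[[axis]], `[[`, "key_genes")
      if (length(kg) >= 2) {
        ov <- shared_and_specific(kg)
        jsonlite::write_json(ov, file.path(cfg$out_dir,
                                           sprintf("key_genes_%s_overlap.json", axis)),
                             auto_unbox = TRUE, null = "null")
      }
    }
    nets
  })
  counts$disease_edges <- length(nets$all$all$selected)
  counts$disease_key_genes <- length(nets$all$all$key_genes)

  # stage 5: enrichment on the disease network's key genes
  enr <- run_stage("enrich", {
    sets <- load_gmt(file.path(data_dir, "pathways.gmt"))
    kg <- nets$all$all$key_genes
    if (length(kg)) {
      e <- enrich_pathways(kg, sets, bg$genes, alpha = cfg$alpha_enrich)
      write_tsv_file(e, file.path(cfg$out_dir, "enrichment_all.tsv"))
      e
    } else {
      ssn_log("no key genes in the disease network; enrichment skipped")
      NULL
    }
  })
  counts$enriched_pathways <- if (is.null(enr)) 0L else sum(enr$enriched)

  # stage 6: prognosis
  prog <- run_stage("prognosis", {
    features <- edge_features(ssn)
    surv <- clinical[, c("sample_id", "time", "event")]
    screen <- univariate_cox_screen(features, surv, alpha = cfg$alpha_screen)
    write_tsv_file(screen, file.path(cfg$out_dir, "cox_screen.tsv"))
    kept <- screen$edge[screen$keep]
    if (length(kept) < 2) stopf("fewer than 2 edges pass the univariate screen")
    model <- lasso_cox_select(features[, kept, drop = FALSE], surv,
                              folds = cfg$cv_folds, seed = cfg$seed)
    write_risk_model(model, file.path(cfg$out_dir, "risk_model.json"))
    if (model$empty) stopf("LASSO-Cox selected no edges")
    scores <- risk_score(model, features)
    split_ <- median_split(scores)
    km <- km_logrank(surv, split_)
    write_tsv_file(km$curves, file.path(cfg$out_dir, "km_curves.tsv"))
    jsonlite::write_json(list(logrank_chisq = km$logrank_chisq,
                              logrank_p = km$logrank_p,
                              median_score = split_$median,
                              n_high = length(split_$high),
                              n_low = length(split_$low)),
                         file.path(cfg$out_dir, "km_logrank.json"),
                         auto_unbox = TRUE, digits = NA)
    list(screen = screen, model = model, km = km)
  })
  counts$screened_edges <- sum(prog$screen$keep)
  counts$model_edges <- length(prog$model$edges)
  counts$logrank_p <- prog$km$logrank_p

  # provenance
  snapshot <- cfg
  snapshot$sim_config <- if (!is.null(cfg$sim_config)) unclass(cfg$sim_config)
  jsonlite::write_json(unclass(snapshot),
                       file.path(cfg$out_dir, "config_snapshot.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  data_files <- list.files(data_dir, full.names = TRUE)
  manifest <- list(
    package = "ssnet",
    package_version = as.character(utils::packageVersion("ssnet")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    stages = c("build-background", "build-ssn", "group-networks",
               "enrich", "prognosis"),
    input_hashes = as.list(stats::setNames(tools::md5sum(data_files),
                                           basename(data_files))),
    counts = counts
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(cfg$out_dir)
}
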