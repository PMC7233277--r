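# Edge-biomarker survival modeling: univariate Cox screen of delta-PCC
# features, LASSO-Cox selection with cross-validation, risk scoring,
# median split, Kaplan-Meier / log-rank, and transfer to an external
# cohort with missing-edge reporting.

#' Univariate Cox screen of edge features
#'
#' Fits one single-covariate proportional-hazards model per edge feature
#' and keeps edges whose Wald p-value is strictly below `alpha`.
#' Zero-variance or non-convergent features are dropped with a log entry.
#'
#' @param features numeric matrix, samples x edges, edge-id colnames,
#'   sample-id rownames.
#' @param surv data.frame with `sample_id`, `time`, `event` (0/1).
#' @param alpha screening level, default 0.05.
#' @param test `"wald"` (default) or `"lrt"` (likelihood ratio).
#' @param ties tie handling passed to [survival::coxph()], default
#'   `"efron"`.
#' @return data.frame with `edge`, `coef`, `hr`, `p`, `keep`, sorted by p.
#' @export
univariate_cox_screen <- function(features, surv, alpha = 0.05,
                                  test = c("wald", "lrt"), ties = "efron") {
  test <- match.arg(test)
  surv <- align_survival(features, surv)
  y <- survival::Surv(surv$time, surv$event)
  res <- lapply(colnames(features), function(e) {
    x <- features[, e]
    if (!is.finite(stats::sd(x)) || stats::sd(x) == 0) {
      ssn_log("edge %s has zero variance; dropped from the screen", e)
      return(NULL)
    }
    fit <- tryCatch(
      survival::coxph(y ~ x, ties = ties),
      error = function(err) NULL, warning = function(w) {
        # ran out of iterations / infinite coefficient: refit quietly, then
        # judge by the finite-ness of the estimate
        suppressWarnings(survival::coxph(y ~ x, ties = ties))
      })
    if (is.null(fit) || !is.finite(stats::coef(fit)[1])) {
      ssn_log("edge %s: non-convergent univariate Cox fit; dropped", e)
      return(NULL)
    }
    p <- if (test == "wald") summary(fit)$coefficients[1, "Pr(>|z|)"]
         else stats::pchisq(2 * diff(fit$loglik), df = 1, lower.tail = FALSE)
    data.frame(edge = e, coef = unname(stats::coef(fit)[1]),
               hr = exp(unname(stats::coef(fit)[1])), p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(edge = character(0), coef = numeric(0),
                      hr = numeric(0), p = numeric(0), keep = logical(0)))
  out$keep <- out$p < alpha
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

align_survival <- function(features, surv) {
  if (is.null(rownames(features))) stopf("features needs sample rownames")
  miss <- setdiff(rownames(features), surv$sample_id)
  if (length(miss))
    stopf("no survival record for sample(s): %s", paste(utils::head(miss, 5), collapse = ", "))
  surv <- surv[match(rownames(features), surv$sample_id), , drop = FALSE]
  if (any(surv$time < 0)) stopf("negative survival times")
  if (!all(surv$event %in% c(0, 1))) stopf("event must be 0/1")
  surv
}

#' LASSO-Cox selection of edge biomarkers
#'
#' L1-penalized proportional-hazards path over the screened edges; the
#' penalty is chosen by k-fold cross-validation minimizing the partial-
#' likelihood deviance (the LASSO-Cox analogue of the smallest
#' cross-validated error). Fold assignment is seeded so the selection is
#' reproducible.
#'
#' @param features samples x edges matrix restricted to screened edges.
#' @param surv survival table (see [univariate_cox_screen()]).
#' @param folds number of CV folds, default 4.
#' @param seed RNG seed for the fold assignment.
#' @param lambda `"lambda.min"` (default) or `"lambda.1se"`.
#' @param refit refit an unpenalized multivariate Cox model on the selected
#'   edges and store its coefficients instead of the penalized ones;
#'   default FALSE.
#' @return object of class `risk_model`: list with `edges`, `coefficients`,
#'   `lambda`, `cv_folds`, `seed`, `refit`, `n_samples`, `n_candidates`.
#'   If every coefficient is zero at the chosen penalty, `edges` is empty
#'   and the model is flagged `empty = TRUE`.
#' @export
lasso_cox_select <- function(features, surv, folds = 4, seed = 1,
                             lambda = c("lambda.min", "lambda.1se"),
                             refit = FALSE) {
  lambda <- match.arg(lambda)
  surv <- align_survival(features, surv)
  if (ncol(features) < 2) stopf("need at least 2 candidate edges for the LASSO path")
  if (sum(surv$event) < 2 * folds)
    stopf("too few events (%d) for %d-fold cross-validation", sum(surv$event), folds)
  y <- survival::Surv(surv$time, surv$event)
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(folds), nrow(features)))
  cv <- glmnet::cv.glmnet(features, y, family = "cox", foldid = foldid,
                          type.measure = "deviance")
  lam <- cv[[lambda]]
  beta <- as.matrix(stats::coef(cv, s = lam))[, 1]
  nz <- beta[beta != 0]
  empty <- length(nz) == 0
  if (empty) ssn_log("LASSO-Cox selected no edges at %s = %.4g", lambda, lam)
  model <- structure(
    list(edges = names(nz), coefficients = unname(nz), lambda = lam,
         lambda_rule = lambda, cv_folds = folds, seed = seed, refit = refit,
         n_samples = nrow(features), n_candidates = ncol(features),
         empty = empty),
    class = "risk_model"
  )
  if (refit && !empty) model <- refit_risk_model(model, features, surv)
  model
}

#' @export
print.risk_model <- function(x, ...) {
  cat("Risk model:", length(x$edges), "edge biomarkers (lambda =",
      signif(x$lambda, 4), ",", x$cv_folds, "fold CV, seed", x$seed, ")\n")
  invisible(x)
}

refit_risk_model <- function(model, features, surv, ties = "efron") {
  surv <- align_survival(features, surv)
  X <- features[, model$edges, drop = FALSE]
  fit <- survival::coxph(survival::Surv(surv$time, surv$event) ~ X, ties = ties)
  model$coefficients <- unname(stats::coef(fit))
  model$refit <- TRUE
  model
}

#' Risk score: the model's linear predictor
#'
#' `score_s = sum_e coef_e * deltaPCC_{s,e}` over the model's edges.
#'
#' @param model a `risk_model`.
#' @param features samples x edges matrix containing every model edge.
#' @return named numeric vector of per-sample scores.
#' @export
risk_score <- function(model, features) {
  if (model$empty || !length(model$edges)) stopf("empty risk model")
  miss <- setdiff(model$edges, colnames(features))
  if (length(miss))
    stopf("features lack %d model edges (use apply_external for transfer)",
          length(miss))
  drop(features[, model$edges, drop = FALSE] %*% model$coefficients)
}

#' Median split into high- and low-risk groups
#'
#' High risk is `score > median`; ties at the median go to the low-risk
#' group so the split is deterministic. A degenerate all-equal score vector
#' yields an empty high-risk group with a logged warning.
#'
#' @param scores named numeric vector of risk scores.
#' @return list with `high` and `low` (character vectors of sample ids)
#'   and `median`.
#' @export
median_split <- function(scores) {
  if (length(scores) < 2) stopf("need at least 2 samples")
  med <- stats::median(scores)
  high <- names(scores)[scores > med]
  low <- names(scores)[scores <= med]
  if (!length(high))
    warning("degenerate risk scores: high-risk group is empty")
  list(high = high, low = low, median = med)
}

#' Kaplan-Meier curves and log-rank test for two risk groups
#'
#' @param surv survival table with `sample_id`, `time`, `event`.
#' @param groups list with `high` and `low` sample-id vectors.
#' @return list with `curves` (data.frame: `group`, `time`, `n_risk`,
#'   `n_event`, `surv`), `logrank_chisq`, `logrank_p` (NA with a log entry
#'   when the test is undefined).
#' @export
km_logrank <- function(surv, groups) {
  ids <- c(groups$high, groups$low)
  if (!length(groups$high) || !length(groups$low))
    stopf("both risk groups must be non-empty")
  surv <- surv[match(ids, surv$sample_id), , drop = FALSE]
  grp <- factor(rep(c("high", "low"), c(length(groups$high), length(groups$low))),
                levels = c("high", "low"))
  y <- survival::Surv(surv$time, surv$event)
  fit <- survival::survfit(y ~ grp)
  strata_grp <- rep(sub("^grp=", "", names(fit$strata)), fit$strata)
  curves <- data.frame(group = strata_grp, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       surv = fit$surv, stringsAsFactors = FALSE)
  lr <- tryCatch(survival::survdiff(y ~ grp), error = function(e) NULL)
  if (is.null(lr) || !is.finite(lr$chisq)) {
    ssn_log("log-rank statistic undefined for these groups")
    chisq <- NA_real_; p <- NA_real_
  } else {
    chisq <- lr$chisq
    p <- stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE)
  }
  list(curves = curves, logrank_chisq = chisq, logrank_p = p)
}

#' Apply a trained risk model to an external cohort
#'
#' Model edges absent from the external feature matrix are dropped from
#' the linear predictor; their identity and count are reported. Scores use
#' the remaining terms.
#'
#' @param model a `risk_model`.
#' @param external_features samples x edges matrix from the external
#'   cohort's own differential networks.
#' @return list with `scores`, `omitted` (character vector of dropped
#'   edges), `n_omitted`, `used` (edges entering the score).
#' @export
apply_external <- function(model, external_features) {
  if (model$empty || !length(model$edges)) stopf("empty risk model")
  present <- model$edges %in% colnames(external_features)
  if (!any(present))
    stopf("none of the %d model edges are present in the external features",
          length(model$edges))
  omitted <- model$edges[!present]
  if (length(omitted))
    ssn_log("%d model edges omitted from the external cohort", length(omitted))
  used <- model$edges[present]
  scores <- drop(external_features[, used, drop = FALSE] %*%
                   model$coefficients[present])
  list(scores = scores, omitted = omitted, n_omitted = length(omitted),
       used = used)
}

#' Serialize a risk model to JSON
#' @param model a `risk_model`. @param path output file.
#' @export
write_risk_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a risk model from JSON
#' @param path model JSON file.
#' @export
read_risk_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$edges <- as.character(obj$edges %||% character(0))
  obj$coefficients <- as.numeric(obj$coefficients %||% numeric(0))
  structure(obj, class = "risk_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
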