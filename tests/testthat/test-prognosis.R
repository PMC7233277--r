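# synthetic survival cohort with a single prognostic feature among noise
make_surv_fixture <- function(n = 200, p = 30, beta = 1.5, seed = 501,
                              censoring = 0.3) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", 1:n), paste0("ga|gb", 1:p)))
  surv <- sample_survival(X, setNames(beta, colnames(X)[1]),
                          baseline_rate = 1e-3, censoring_rate = censoring,
                          seed = seed + 1)
  list(X = X, surv = surv)
}

test_that("univariate screen keeps the prognostic edge and drops degenerates", {
  fx <- make_surv_fixture()
  X <- fx$X
  X[, 2] <- 7  # constant: must be dropped with a log entry
  expect_message(res <- univariate_cox_screen(X, fx$surv), "zero variance")
  expect_false(colnames(X)[2] %in% res$edge)
  hit <- res[res$edge == colnames(X)[1], ]
  expect_true(hit$keep)
  expect_lt(hit$p, 1e-6)
  expect_gt(hit$coef, 0)
  # noise features are retained at roughly the screening level
  noise_keep <- mean(res$keep[res$edge != colnames(X)[1]])
  expect_lt(noise_keep, 0.2)
})

test_that("screen retains ~alpha of edges once survival is permuted", {
  fx <- make_surv_fixture(n = 150, p = 40, beta = 0)
  rates <- vapply(1:5, function(r) {
    set.seed(510 + r)
    surv <- fx$surv
    perm <- sample(nrow(surv))
    surv$time <- surv$time[perm]
    surv$event <- surv$event[perm]
    mean(univariate_cox_screen(fx$X, surv)$keep)
  }, numeric(1))
  expect_lt(mean(rates), 0.12)
})

test_that("wald and likelihood-ratio screens broadly agree", {
  fx <- make_surv_fixture(n = 120, p = 10)
  w <- univariate_cox_screen(fx$X, fx$surv, test = "wald")
  l <- univariate_cox_screen(fx$X, fx$surv, test = "lrt")
  merged <- merge(w, l, by = "edge")
  expect_gt(cor(-log10(merged$p.x), -log10(merged$p.y)), 0.98)
})

test_that("lasso_cox_select recovers a strong edge and is seed-deterministic", {
  fx <- make_surv_fixture(n = 200, p = 30, beta = 1.5)
  model <- lasso_cox_select(fx$X, fx$surv, folds = 4, seed = 9)
  expect_s3_class(model, "risk_model")
  expect_true(colnames(fx$X)[1] %in% model$edges)
  expect_gt(model$coefficients[model$edges == colnames(fx$X)[1]], 0)
  expect_equal(model$cv_folds, 4)
  model2 <- lasso_cox_select(fx$X, fx$surv, folds = 4, seed = 9)
  expect_identical(model$edges, model2$edges)
  expect_identical(model$coefficients, model2$coefficients)
})

test_that("a duplicated informative column leaves the fitted scores essentially unchanged", {
  fx <- make_surv_fixture(n = 150, p = 10, beta = 1.5)
  m1 <- lasso_cox_select(fx$X, fx$surv, seed = 3)
  X2 <- cbind(fx$X, dup = fx$X[, 1])
  colnames(X2)[ncol(X2)] <- "dup|edge"
  m2 <- lasso_cox_select(X2, fx$surv, seed = 3)
  expect_gt(length(m2$edges), 0)
  s1 <- risk_score(m1, fx$X)
  s2 <- risk_score(m2, X2)
  expect_gt(cor(s1, s2), 0.95)
})

test_that("an unpenalized refit is available and changes only coefficients", {
  fx <- make_surv_fixture(n = 150, p = 10, beta = 1.5)
  pen <- lasso_cox_select(fx$X, fx$surv, seed = 5)
  ref <- lasso_cox_select(fx$X, fx$surv, seed = 5, refit = TRUE)
  expect_identical(pen$edges, ref$edges)
  expect_true(ref$refit)
  expect_false(isTRUE(all.equal(pen$coefficients, ref$coefficients)))
})

test_that("risk_score is the dot product and affine-equivariant", {
  model <- structure(list(edges = c("e1", "e2"), coefficients = c(2, -1),
                          empty = FALSE), class = "risk_model")
  X <- matrix(c(0.5, 0, 0.1, 0.2), 2, 2,
              dimnames = list(c("s1", "s2"), c("e1", "e2")))
  expect_equal(unname(risk_score(model, X)), c(2 * 0.5 - 1 * 0.1, -0.2))
  expect_equal(unname(risk_score(model, X * 0)), c(0, 0))
  set.seed(502)
  Xr <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), c("e1", "e2")))
  s <- risk_score(model, Xr)
  expect_equal(unname(s), drop(Xr %*% c(2, -1)), ignore_attr = TRUE)
  model3 <- model; model3$coefficients <- 3 * model$coefficients
  expect_equal(risk_score(model3, Xr), 3 * s)
  expect_equal(median_split(3 * s), c(median_split(s)[1:2], median = list(3 * median(s))),
               ignore_attr = TRUE)
})

test_that("median_split sends ties to the low-risk group", {
  s <- setNames(c(1, 2, 3), c("a", "b", "c"))
  sp <- median_split(s)
  expect_equal(sp$high, "c")
  expect_setequal(sp$low, c("a", "b"))
  expect_warning(sp2 <- median_split(setNames(rep(1, 4), letters[1:4])),
                 "degenerate")
  expect_length(sp2$high, 0)
  expect_length(sp2$low, 4)
  set.seed(503)
  sr <- setNames(rnorm(21), paste0("s", 1:21))
  spr <- median_split(sr)
  expect_setequal(spr$high, names(sr)[sr > median(sr)])
  expect_setequal(spr$low, names(sr)[sr <= median(sr)])
})

test_that("km_logrank matches a hand-computed log-rank table on toy data", {
  surv <- data.frame(sample_id = c("a", "b", "c", "d"),
                     time = c(1, 2, 3, 4), event = 1)
  out <- km_logrank(surv, list(high = c("a", "b"), low = c("c", "d")))
  # hand calculation: at t=1 group1 1/2 at risk of 4; t=2 1/1 of 3;
  # t=3 0/1 of 2; t=4 0/1 of 1 -> O1=2, E1=1/2+1/3=1.33; V=sum of
  # hypergeometric variances n1 n2 d (n-d) / (n^2 (n-1)) = 1/4+2/9
  O1 <- 2; E1 <- 2 / 4 + 1 / 3
  V <- (2 * 2 * 1 * 3) / (16 * 3) + (1 * 2 * 1 * 2) / (9 * 2)
  expect_equal(out$logrank_chisq, (O1 - E1)^2 / V, tolerance = 1e-10)
  expect_equal(out$logrank_p, pchisq((O1 - E1)^2 / V, 1, lower.tail = FALSE))
  # KM curves: high group drops to 0.5 then 0
  hi <- out$curves[out$curves$group == "high", ]
  expect_equal(hi$surv, c(0.5, 0))
})

test_that("identical survival in both groups gives a near-zero statistic", {
  set.seed(504)
  times <- rexp(40, 0.01)
  surv <- data.frame(sample_id = paste0("s", 1:80),
                     time = rep(times, 2), event = 1)
  out <- km_logrank(surv, list(high = paste0("s", 1:40),
                               low = paste0("s", 41:80)))
  expect_lt(out$logrank_chisq, 1e-8)
  expect_gt(out$logrank_p, 0.99)
})

test_that("a strong group hazard contrast is detected decisively", {
  set.seed(505)
  n <- 100
  t_high <- rexp(n, 3e-3); t_low <- rexp(n, 1e-3)
  surv <- data.frame(sample_id = paste0("s", 1:(2 * n)),
                     time = c(t_high, t_low), event = 1)
  out <- km_logrank(surv, list(high = paste0("s", 1:n),
                               low = paste0("s", (n + 1):(2 * n))))
  expect_lt(out$logrank_p, 1e-4)
})

test_that("apply_external drops exactly the missing edges and reports them", {
  model <- structure(list(edges = paste0("e", 1:10),
                          coefficients = rnorm(10), empty = FALSE),
                     class = "risk_model")
  set.seed(506)
  X <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(paste0("s", 1:50), paste0("e", 1:10)))
  full <- apply_external(model, X)
  expect_length(full$omitted, 0)
  expect_equal(full$scores, risk_score(model, X))

  Xm <- X[, -c(3, 7)]
  expect_message(part <- apply_external(model, Xm), "2 model edges omitted")
  expect_equal(part$n_omitted, 2L)
  expect_setequal(part$omitted, c("e3", "e7"))
  mask <- model$coefficients
  mask[c(3, 7)] <- 0
  expect_equal(unname(part$scores), unname(drop(X %*% mask)))

  expect_error(apply_external(model, X[, 0]), "none of the")
})

test_that("risk models round-trip through JSON", {
  fx <- make_surv_fixture(n = 120, p = 8, beta = 1.5)
  model <- lasso_cox_select(fx$X, fx$surv, seed = 2)
  path <- tempfile(fileext = ".json")
  write_risk_model(model, path)
  back <- read_risk_model(path)
  expect_equal(back$edges, model$edges)
  expect_equal(back$coefficients, model$coefficients)
  expect_equal(back$lambda, model$lambda)
  expect_equal(risk_score(back, fx$X), risk_score(model, fx$X))
})
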