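test_that("intercept-only fit recovers the logit of the event rate", {
  y <- c(rep(1, 21), rep(0, 75))
  fit <- fit_logistic(NULL, y)
  expect_equal(unname(fit$coefficients[1]), log(21 / 75), tolerance = 1e-6)
  expect_equal(fit$aic, 2 - 2 * fit$log_likelihood)
})

test_that("degenerate designs raise informative errors", {
  y <- rep(c(0, 1), 10)
  expect_error(fit_logistic(data.frame(x = rnorm(20)), rep(1, 20)),
               "single class")
  X <- data.frame(a = rnorm(20))
  X$b <- 2 * X$a
  expect_error(fit_logistic(X, y), "rank deficient.*b")
})

test_that("coefficient estimates achieve nominal coverage and flat nulls", {
  set.seed(55)
  cover <- 0
  reps <- 120
  for (i in 1:reps) {
    x <- rnorm(250)
    y <- rbinom(250, 1, expit(-0.5 + 0.7 * x))
    f <- fit_logistic(data.frame(x = x), y)
    ci <- f$coefficients[["x"]] + c(-1.96, 1.96) * f$se[["x"]]
    if (ci[1] <= 0.7 && 0.7 <= ci[2]) cover <- cover + 1
  }
  expect_gt(cover / reps, 0.88)
  # null screening keeps ~20%
  set.seed(56)
  ps <- replicate(400, univariable_lrt(rnorm(120), rbinom(120, 1, 0.4))$p)
  expect_lt(abs(mean(ps < 0.2) - 0.2), 0.065)
})

test_that("standard errors match the numerical Hessian on a toy fit", {
  set.seed(3)
  X <- data.frame(x1 = rnorm(80), x2 = rnorm(80))
  y <- rbinom(80, 1, expit(0.3 + 0.8 * X$x1 - 0.5 * X$x2))
  f <- fit_logistic(X, y)
  ll <- function(b) {
    eta <- b[1] + b[2] * X$x1 + b[3] * X$x2
    sum(y * eta - log(1 + exp(eta)))
  }
  H <- optimHess(unname(f$coefficients), ll)
  se_num <- sqrt(diag(solve(-H)))
  expect_equal(unname(f$se), se_num, tolerance = 1e-4)
})

test_that("published marker screening p values follow from the 2x2 counts", {
  ft <- fixture_tables()
  # HER2, group 1: 1/17 positive vs 19/57 negative (94 informative patients)
  her2 <- c(rep(1, 18), rep(0, 76))
  y1 <- c(rep(1, 1), rep(0, 17), rep(1, 19), rep(0, 57))
  expect_equal(sum(her2), sum(ft$her2_response_g1["positive", ]))
  p_her2 <- univariable_lrt(her2, y1)$p
  expect_equal(round(p_her2, 3), 0.043, tolerance = 0.0015)
  # CD44, group 2: 8/19 positive vs 1/15 negative
  cd44 <- c(rep(1, 27), rep(0, 16))
  y2 <- c(rep(1, 8), rep(0, 19), rep(1, 1), rep(0, 15))
  p_cd44 <- univariable_lrt(cd44, y2)$p
  expect_equal(round(p_cd44, 3), 0.051, tolerance = 0.0015)
})

test_that("LASSO spans the unpenalized and fully shrunk limits", {
  set.seed(77)
  n <- 500
  X <- matrix(rnorm(n * 7), n, 7,
              dimnames = list(NULL, paste0("f", 1:7)))
  y <- rbinom(n, 1, expit(1.2 * X[, 1] - 1.2 * X[, 2]))
  fit <- glmnet::glmnet(X, y, family = "binomial")
  b_small <- as.matrix(coef(fit, s = min(fit$lambda)))[-1, 1]
  expect_equal(sum(b_small != 0), 7)
  b_big <- as.matrix(coef(fit, s = 10))[-1, 1]
  expect_equal(sum(b_big != 0), 0)
})

test_that("informative features are selected consistently over seeds", {
  hits <- 0
  runs <- 40
  for (i in seq_len(runs)) {
    set.seed(1000 + i)
    n <- 500
    X <- matrix(rnorm(n * 7), n, 7,
                dimnames = list(NULL, paste0("f", 1:7)))
    y <- rbinom(n, 1, expit(1.3 * X[, 1] - 1.3 * X[, 2]))
    sel <- lasso_select(X, y, seed = i)
    if (all(c("f1", "f2") %in% sel)) hits <- hits + 1
  }
  expect_gte(hits / runs, 0.9)
})

test_that("the twelve-model suite respects its covariate algebra", {
  spec <- cohort_spec(n_patients = 300, prev_response = 0.3,
                      beta = c("(Intercept)" = NA, her2 = -1.5, cd44 = 1,
                               ct_t34a = -0.8, b1_f1 = 0.9),
                      seed = 19)
  ch <- generate_cohort(spec)
  suite <- build_model_suite(ch$features, ch$labels,
                             clinical_terms = c("histology_squamous",
                                                "ct_t34a"),
                             radiomic_terms = c("b1_f1", "b2_f1"))
  expect_length(suite, 12)
  expect_setequal(suite$M3$covariates,
                  union(suite$M1$covariates, suite$M2$covariates))
  expect_setequal(suite$M10$covariates,
                  c(suite$M1$covariates, "her2", "cd44"))
  # markers carry real signal: adding them improves AIC over M1
  expect_lt(suite$M10$fit$aic, suite$M1$fit$aic)
  # nesting: M3 log-likelihood >= both M1 and M2
  expect_gte(suite$M3$fit$log_likelihood, suite$M1$fit$log_likelihood - 1e-8)
  expect_gte(suite$M3$fit$log_likelihood, suite$M2$fit$log_likelihood - 1e-8)
  # AIC identity across the suite
  for (m in suite) {
    expect_equal(m$fit$aic, 2 * m$fit$k - 2 * m$fit$log_likelihood)
  }
})

test_that("marker models drop marker-missing cases only", {
  feats <- fixture_cohort(2)
  cl <- read_clinical(feats)
  dat <- data.frame(
    histology_squamous = as.numeric(cl$histology == "squamous"),
    ct_t34a = as.numeric(cl$ct_stage == "T3-4a"),
    her2 = cl$her2, cd44 = cl$cd44,
    rad1 = seq_len(nrow(cl)) / nrow(cl))
  y <- as.integer(cl$response == "pCR")
  suite <- build_model_suite(dat, y, radiomic_terms = "rad1")
  expect_equal(suite$M1$n, 43)
  expect_equal(suite$M4$n, 42)   # 1 missing HER2 excluded
  expect_equal(suite$M7$n, 43)   # CD44 complete
  expect_equal(suite$M10$n, 42)
})
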