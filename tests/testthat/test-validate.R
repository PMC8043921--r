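test_that("Nagelkerke R2 hits its analytic anchors", {
  # null model
  y <- c(rep(1, 5), rep(0, 15))
  ll0 <- bernoulli_ll(rep(mean(y), 20), y)
  expect_equal(nagelkerke_r2(ll0, ll0, 20), 0)
  # near-perfect separation -> R2 -> 1
  p_perf <- ifelse(y == 1, 1 - 1e-10, 1e-10)
  expect_equal(nagelkerke_r2(bernoulli_ll(p_perf, y), ll0, 20), 1,
               tolerance = 1e-6)
  # toy fit against direct log-likelihood computation
  yy <- c(0, 0, 0, 1, 1, 1)
  x <- 1:6
  f <- suppressWarnings(glm(yy ~ x, family = binomial()))
  ll1 <- sum(yy * log(fitted(f)) + (1 - yy) * log(1 - fitted(f)))
  ll0b <- sum(yy * log(0.5) + (1 - yy) * log(0.5))
  r2 <- nagelkerke_r2(as.numeric(logLik(f)), ll0b, 6)
  expect_equal(r2, (1 - exp((2 / 6) * (ll0b - ll1))) /
                 (1 - exp((2 / 6) * ll0b)), tolerance = 1e-8)
})

test_that("Brier, AUC, and discrimination slope match their definitions", {
  y <- c(0, 0, 1, 1)
  expect_equal(brier_score(rep(0.5, 4), y), 0.25)
  expect_equal(brier_score(y, y), 0)
  expect_equal(roc_auc(y, y), 1)
  expect_equal(discrimination_slope(y, y), 1)
  # tie handling against exhaustive pair counting
  p <- c(0.2, 0.4, 0.4, 0.9)
  expect_equal(roc_auc(p, y), o_auc(p, y))
  for (seed in 1:20) {
    set.seed(seed)
    yy <- rbinom(30, 1, 0.4)
    if (length(unique(yy)) < 2) next
    pp <- round(runif(30), 1)  # plenty of ties
    expect_equal(roc_auc(pp, yy), o_auc(pp, yy), tolerance = 1e-12)
    expect_equal(discrimination_slope(pp, yy),
                 mean(pp[yy == 1]) - mean(pp[yy == 0]))
  }
})

test_that("AUC is invariant to strictly monotone transforms", {
  set.seed(8)
  y <- rbinom(50, 1, 0.5)
  p <- runif(50)
  expect_equal(roc_auc(p, y), roc_auc(qlogis(p), y))
  expect_equal(roc_auc(p, y), roc_auc(p^3, y))
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- rbinom(80, 1, 0.4)
  p <- expit(rnorm(80) + y)
  expect_equal(roc_auc(p, y),
               as.numeric(suppressMessages(pROC::auc(y, p))),
               tolerance = 1e-10)
})

test_that("calibration recovers known miscalibration patterns", {
  set.seed(41)
  n <- 1e5
  lp <- rnorm(n, -1, 1.2)
  p <- expit(lp)
  y <- rbinom(n, 1, p)
  cal <- calibration_coefficients(p, y)
  expect_lt(abs(cal[["intercept"]]), 0.05)
  expect_lt(abs(cal[["slope"]] - 1), 0.05)
  # doubled logits -> slope ~ 0.5
  cal2 <- calibration_coefficients(expit(2 * lp), y)
  expect_lt(abs(cal2[["slope"]] - 0.5), 0.05)
  # shifted by +0.5 logits -> calibration-in-the-large ~ -0.5
  cal3 <- calibration_coefficients(expit(lp + 0.5), y)
  expect_lt(abs(cal3[["intercept"]] + 0.5), 0.05)
  expect_error(calibration_coefficients(rep(0.3, 100), rbinom(100, 1, 0.3)),
               "constant")
})

test_that("calibration curve collapses correctly for constant predictions", {
  set.seed(4)
  y <- rbinom(400, 1, 0.25)
  p <- rep(mean(y), 400) + rnorm(400, 0, 1e-6)
  cc <- calibration_curve(p, y, bins = 10)
  expect_lt(abs(mean(cc$groups$obs_rate, na.rm = TRUE) - mean(y)), 0.05)
  set.seed(5)
  pw <- runif(2000)
  yw <- rbinom(2000, 1, pw)
  cw <- calibration_curve(pw, yw)
  expect_lt(max(abs(cw$groups$mean_pred - cw$groups$obs_rate)), 0.12)
})

test_that("null model bootstrap shows (near) zero optimism", {
  set.seed(9)
  y <- rbinom(80, 1, 0.3)
  dat <- data.frame(z = rnorm(80))
  # intercept-only target: validate a model with no informative covariate
  rep0 <- bootstrap_validate(dat, y, terms = character(0), B = 200, seed = 2)
  expect_lt(abs(rep0$measures["optimism", "brier"]), 0.01)
  expect_lt(abs(rep0$measures["optimism", "r2"]), 0.02)
})

test_that("overfit noise models are pulled back toward chance", {
  # pure-noise predictors at n = 60: the corrected AUC estimator is noisy on
  # any single dataset, so average over replicate datasets; the correction
  # should remove most of the apparent optimism above chance
  res <- sapply(1:8, function(ds) {
    set.seed(ds * 100)
    n <- 60
    y <- rbinom(n, 1, 0.4)
    dat <- as.data.frame(matrix(rnorm(n * 10), n, 10))
    names(dat) <- paste0("noise", 1:10)
    r <- bootstrap_validate(dat, y, names(dat), B = 200, seed = ds)
    c(app = r$measures["apparent", "auc"],
      cor = r$measures["corrected", "auc"],
      slope = r$measures["corrected", "cal_slope"],
      check = max(abs(r$measures["corrected", ] -
                        (r$measures["apparent", ] -
                           r$measures["optimism", ])), na.rm = TRUE))
  })
  expect_gt(mean(res["app", ]), 0.65)                 # apparent >> 0.5
  # corrected sits near chance: more than half of the above-chance apparent
  # excess is removed (a residual positive bias is a known property of the
  # estimator at this events-per-variable ratio)
  expect_lt(abs(mean(res["cor", ]) - 0.5),
            0.5 * (mean(res["app", ]) - 0.5))
  expect_gt(mean(res["app", ] - res["cor", ]), 0.1)   # substantial optimism
  expect_lt(mean(res["slope", ]), 0.75)               # shrinkage detected
  expect_lt(max(res["check", ]), 1e-12)               # corrected identity
})

test_that("bootstrap reports are reproducible and convergent in B", {
  set.seed(11)
  n <- 90
  x <- rnorm(n)
  y <- rbinom(n, 1, expit(0.8 * x - 0.5))
  dat <- data.frame(x = x)
  a <- bootstrap_validate(dat, y, "x", B = 300, seed = 7)
  b <- bootstrap_validate(dat, y, "x", B = 300, seed = 7)
  expect_identical(a$measures, b$measures)
  c1 <- bootstrap_validate(dat, y, "x", B = 1000, seed = 8)
  c2 <- bootstrap_validate(dat, y, "x", B = 2000, seed = 9)
  expect_lt(abs(c1$measures["corrected", "auc"] -
                  c2$measures["corrected", "auc"]), 0.005)
})

test_that("pipeline refit policy charges selection optimism", {
  set.seed(13)
  n <- 70
  y <- rbinom(n, 1, 0.35)
  dat <- as.data.frame(matrix(rnorm(n * 12), n, 12))
  names(dat) <- paste0("f", 1:12)
  pick2 <- function(d, yy) {
    ps <- vapply(names(d), function(f) univariable_lrt(d[[f]], yy)$p, 0)
    names(sort(ps))[1:2]
  }
  rep_fixed <- bootstrap_validate(dat, y, pick2(dat, y), B = 150, seed = 5)
  rep_pipe <- bootstrap_validate(dat, y, pick2(dat, y), B = 150, seed = 5,
                                 refit_policy = "pipeline",
                                 pipeline_fn = pick2)
  # repeating the selection inside each resample charges at least as much
  # optimism as refitting the fixed set
  expect_gte(rep_pipe$measures["optimism", "auc"],
             rep_fixed$measures["optimism", "auc"] - 0.02)
  app <- rep_pipe$measures["apparent", "auc"]
  expect_gt(app - rep_pipe$measures["corrected", "auc"], 0.02)
  expect_lte(rep_pipe$measures["corrected", "auc"],
             rep_fixed$measures["corrected", "auc"] + 0.02)
})
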