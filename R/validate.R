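# Performance measures (overall, discrimination, calibration) and Harrell's
# bootstrap optimism correction.

#' Nagelkerke R2
#'
#' Cox-Snell R2 = 1 - exp((2/n)(LL0 - LL1)) divided by its attainable
#' maximum 1 - exp((2/n) LL0).
#'
#' @param ll_model,ll_null log-likelihoods of the model and of the
#'   intercept-only model on the same data.
#' @param n number of observations.
#' @return value in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(ll_model, ll_null, n) {
  abort_if(ll_model < ll_null - 1e-8,
           "model log-likelihood below null log-likelihood")
  cs <- 1 - exp((2 / n) * (ll_null - ll_model))
  cs_max <- 1 - exp((2 / n) * ll_null)
  if (cs_max <= 0) return(0)
  min(cs / cs_max, 1)
}

bernoulli_ll <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

#' Brier score
#' @param p predicted probabilities.
#' @param y binary outcome.
#' @return mean squared prediction error in `[0, 1]`.
#' @export
brier_score <- function(p, y) {
  stopifnot(length(p) == length(y), all(p >= 0 & p <= 1))
  mean((p - as.numeric(y))^2)
}

#' Area under the ROC curve (Mann-Whitney, ties count one half)
#' @param p predicted probabilities (or any risk score).
#' @param y binary outcome, both classes present.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(p, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  abort_if(n1 == 0 || n0 == 0, "AUC undefined: one outcome class only")
  r <- rank(p)  # midranks handle ties as half-wins
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Discrimination slope
#'
#' Mean predicted probability in events minus non-events.
#' @inheritParams roc_auc
#' @return value in `[-1, 1]`.
#' @export
discrimination_slope <- function(p, y) {
  y <- as.integer(y)
  abort_if(!any(y == 1) || !any(y == 0),
           "discrimination slope undefined: one outcome class only")
  mean(p[y == 1]) - mean(p[y == 0])
}

#' Logistic recalibration coefficients
#'
#' Slope b from the refit y ~ a + b logit(p); intercept reported as
#' calibration-in-the-large: a from y ~ a + offset(logit(p)) (slope fixed
#' at 1). Probabilities are clipped to `[clip, 1 - clip]` (flagged when
#' clipping occurs).
#'
#' @param p predicted probabilities.
#' @param y binary outcome.
#' @param clip clipping bound, default 1e-8.
#' @return named vector `c(intercept, slope)` with attribute `clipped`.
#' @export
calibration_coefficients <- function(p, y, clip = 1e-8) {
  y <- as.integer(y)
  clipped <- any(p < clip | p > 1 - clip)
  p <- pmin(pmax(p, clip), 1 - clip)
  lp <- logit(p)
  abort_if(sd(lp) == 0, "calibration slope undefined: constant predictions")
  slope_fit <- suppressWarnings(glm(y ~ lp, family = binomial()))
  int_fit <- suppressWarnings(glm(y ~ offset(lp), family = binomial()))
  out <- c(intercept = unname(coef(int_fit)[1]),
           slope = unname(coef(slope_fit)[2]))
  attr(out, "clipped") <- clipped
  out
}

#' Grouped calibration curve data
#'
#' Observed event rate versus mean prediction in quantile bins (deciles by
#' default) plus a lowess smoother, for plotting against the ideal diagonal.
#'
#' @param p predicted probabilities.
#' @param y binary outcome.
#' @param bins number of quantile bins.
#' @return list with `groups` (data.frame `bin`, `n`, `mean_pred`,
#'   `obs_rate`) and `smooth` (data.frame `pred`, `obs`).
#' @export
calibration_curve <- function(p, y, bins = 10) {
  y <- as.integer(y)
  br <- unique(quantile(p, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(p, breaks = br, include.lowest = TRUE)
  groups <- data.frame(
    bin = levels(bin),
    n = as.integer(table(bin)),
    mean_pred = as.numeric(tapply(p, bin, mean)),
    obs_rate = as.numeric(tapply(y, bin, mean)))
  sm <- lowess(p, y, f = 2 / 3)
  list(groups = groups, smooth = data.frame(pred = sm$x, obs = sm$y))
}

# All six measures at once. Unlike the exported nagelkerke_r2 (which asserts
# the nested-MLE inequality), the R2 here may go negative: when an overfit
# model is scored on test data its likelihood can fall below the null.
# Constant predictions (intercept-only models) leave the calibration slope
# undefined (NA); calibration-in-the-large is still computed via the offset
# fit. Probabilities are clipped to [0.5/n, 1 - 0.5/n] so that separated
# bootstrap refits yield large-but-bounded test measures instead of
# divergent ones.
measure_performance <- function(p, y, ll_model = NULL, ll_null = NULL,
                                clip = NULL) {
  y <- as.integer(y)
  n <- length(y)
  if (is.null(clip)) clip <- max(1e-8, 0.5 / n)
  p <- pmin(pmax(p, clip), 1 - clip)
  if (is.null(ll_model)) ll_model <- bernoulli_ll(p, y)
  if (is.null(ll_null)) ll_null <- bernoulli_ll(rep(mean(y), n), y)
  cs <- 1 - exp((2 / n) * (ll_null - ll_model))
  cs_max <- 1 - exp((2 / n) * ll_null)
  r2 <- if (cs_max > 0) min(cs / cs_max, 1) else 0
  lp <- logit(p)
  cal_int <- unname(coef(suppressWarnings(
    glm(y ~ offset(lp), family = binomial())))[1])
  cal_slope <- if (sd(lp) > 0) {
    unname(coef(suppressWarnings(glm(y ~ lp, family = binomial())))[2])
  } else NA_real_
  c(r2 = r2,
    brier = brier_score(p, y),
    auc = roc_auc(p, y),
    ds = discrimination_slope(p, y),
    cal_intercept = cal_int,
    cal_slope = cal_slope)
}

#' Bootstrap optimism-corrected internal validation
#'
#' Harrell's procedure: for each of B outcome-stratified bootstrap resamples
#' the model is refit (per `refit_policy`), its performance measured on the
#' resample (boot-apparent) and on the original data (boot-test); optimism is
#' the mean difference, and corrected = apparent - optimism for each of the
#' six measures (Nagelkerke R2, Brier, AUC, discrimination slope, calibration
#' intercept and slope). Resamples where the refit fails are dropped and
#' counted; more than `max_failure_rate` failures is an error.
#'
#' @param data covariate data.frame.
#' @param y binary outcome.
#' @param terms character vector: covariates of the model under validation.
#' @param B bootstrap repetitions (the study convention is 20000; desk-scale
#'   analyses use fewer).
#' @param seed integer seed.
#' @param refit_policy `"fixed"` refits the coefficients of the fixed
#'   covariate set per resample; `"pipeline"` re-runs a caller-supplied
#'   selection function (`pipeline_fn(data, y)` returning a term set) inside
#'   each resample so selection optimism is included.
#' @param pipeline_fn selection function for the `"pipeline"` policy.
#' @param max_failure_rate maximum tolerated fraction of failed resamples.
#' @return list of class `performance_report`: `measures` (matrix with rows
#'   apparent/optimism/corrected), `B`, `B_used`, `failures`, `seed`.
#' @export
bootstrap_validate <- function(data, y, terms, B = 1000, seed = 1L,
                               refit_policy = c("fixed", "pipeline"),
                               pipeline_fn = NULL,
                               max_failure_rate = 0.2) {
  refit_policy <- match.arg(refit_policy)
  abort_if(B < 1, "B must be >= 1")
  if (refit_policy == "pipeline") {
    abort_if(is.null(pipeline_fn), "pipeline policy needs `pipeline_fn`")
  }
  y <- as.integer(y)
  data <- as.data.frame(data)
  apparent_fit <- fit_logistic(data[, terms, drop = FALSE], y)
  apparent <- measure_performance(predict(apparent_fit), y,
                                  apparent_fit$log_likelihood,
                                  apparent_fit$null_log_likelihood)
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  opt_sum <- rep(0, length(apparent))
  opt_n <- rep(0L, length(apparent))
  used <- 0L
  failures <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      ids <- c(sample(idx1, length(idx1), replace = TRUE),
               sample(idx0, length(idx0), replace = TRUE))
      res <- tryCatch({
        tms <- if (refit_policy == "pipeline") {
          pipeline_fn(data[ids, , drop = FALSE], y[ids])
        } else terms
        bfit <- fit_logistic(data[ids, tms, drop = FALSE], y[ids])
        boot_app <- measure_performance(predict(bfit), y[ids],
                                        bfit$log_likelihood,
                                        bfit$null_log_likelihood)
        p_test <- predict(bfit, newdata = data)
        boot_test <- measure_performance(p_test, y)
        boot_app - boot_test
      }, error = function(e) NULL)
      if (is.null(res)) {
        failures <- failures + 1L
      } else {
        ok <- !is.na(res)
        opt_sum[ok] <- opt_sum[ok] + res[ok]
        opt_n <- opt_n + as.integer(ok)
        used <- used + 1L
      }
    }
  })
  if (failures / B > max_failure_rate) {
    stop(sprintf(
      "bootstrap failed in %d of %d resamples (> %.0f%%); model too unstable",
      failures, B, 100 * max_failure_rate), call. = FALSE)
  }
  optimism <- ifelse(opt_n > 0, opt_sum / pmax(opt_n, 1L), NA_real_)
  names(optimism) <- names(apparent)
  measures <- rbind(apparent = apparent, optimism = optimism,
                    corrected = apparent - optimism)
  structure(list(measures = measures, B = B, B_used = used,
                 failures = failures, seed = seed,
                 aic = apparent_fit$aic, n = apparent_fit$n),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> B = %d (%d used, %d failed), AIC = %.2f\n",
              x$B, x$B_used, x$failures, x$aic))
  print(round(x$measures, 4))
  invisible(x)
}
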