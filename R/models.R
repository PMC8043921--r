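# The twelve logistic prediction models: clinical (M1), radiomic (M2) and
# clinico-radiomic (M3) reference models, each without markers, plus HER2
# (M4-M6), plus CD44 (M7-M9), and plus both markers (M10-M12). Radiomic
# covariates of M2 are chosen by LASSO from the screened cluster
# representatives and the final models are refit unpenalized.

#' Fit a logistic regression model
#'
#' Maximum likelihood by iteratively reweighted least squares (`stats::glm`),
#' with explicit rank and separation diagnostics.
#'
#' @param X data.frame or matrix of covariates (no intercept column).
#' @param y binary outcome (0/1), both classes present.
#' @return list of class `fitted_logistic`: `coefficients`, `se`,
#'   `log_likelihood`, `null_log_likelihood`, `aic` (2k - 2LL), `n`, `k`,
#'   `converged`, `separation`, `fitted`, `terms` and the underlying `glm`.
#' @export
fit_logistic <- function(X, y) {
  y <- as.integer(y)
  abort_if(length(unique(y)) < 2, "outcome has a single class")
  df <- if (is.null(X) || (!is.null(ncol(X)) && ncol(X) == 0)) {
    data.frame(.y = y)
  } else {
    cbind(data.frame(.y = y), as.data.frame(X))
  }
  abort_if(nrow(df) <= ncol(df), "need n > number of parameters")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(is.na(coef(fit)))) {
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  ll <- as.numeric(logLik(fit))
  k <- length(coef(fit))
  sm <- suppressWarnings(summary(fit))
  structure(list(
    coefficients = coef(fit), se = sm$coefficients[, "Std. Error"],
    log_likelihood = ll,
    null_log_likelihood = -fit$null.deviance / 2,
    aic = 2 * k - 2 * ll, n = length(y), k = k,
    converged = fit$converged, separation = sep,
    fitted = fitted(fit), glm = fit,
    terms = setdiff(names(coef(fit)), "(Intercept)")),
    class = "fitted_logistic")
}

#' Predict event probabilities from a fitted logistic model
#'
#' @param object a `fitted_logistic`.
#' @param newdata covariate data.frame (the training data when omitted).
#' @param ... unused.
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict.fitted_logistic <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(unname(object$fitted))
  unname(predict(object$glm, newdata = as.data.frame(newdata),
                 type = "response"))
}

#' @export
print.fitted_logistic <- function(x, ...) {
  cat(sprintf("<fitted_logistic> n = %d, k = %d, LL = %.3f, AIC = %.2f%s\n",
              x$n, x$k, x$log_likelihood, x$aic,
              if (x$separation) " [separation flagged]" else ""))
  invisible(x)
}

#' Univariable likelihood-ratio screening of candidate features
#'
#' @param features data.frame of candidate covariates.
#' @param y binary outcome.
#' @param threshold keep features with LRT p < threshold (default 0.2).
#' @return data.frame `feature`, `p`, `separation`, `keep`.
#' @export
univariable_screen <- function(features, y, threshold = 0.2) {
  out <- lapply(names(features), function(f) {
    s <- univariable_lrt(features[[f]], y)
    data.frame(feature = f, p = s$p, separation = s$separation,
               keep = s$p < threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' LASSO selection of radiomic features
#'
#' L1-penalized logistic path (glmnet, internally standardized) with the
#' penalty chosen by stratified k-fold cross-validated deviance; the
#' selected set is the nonzero-coefficient support at `lambda.min`
#' (`rule = "1se"` gives the sparser 1-SE choice). An empty selection is
#' allowed and flagged; the caller decides the fallback.
#'
#' @param X matrix/data.frame of candidate features (>= 2 columns).
#' @param y binary outcome.
#' @param nfolds folds for cross-validation (stratified on outcome).
#' @param seed integer seed controlling fold assignment.
#' @param rule `"min"` or `"1se"`.
#' @return character vector of selected feature names, with attributes
#'   `lambda` and `empty` (logical).
#' @export
lasso_select <- function(X, y, nfolds = 5, seed = 1L,
                         rule = c("min", "1se")) {
  rule <- match.arg(rule)
  X <- as.matrix(X)
  abort_if(ncol(X) < 2, "need at least 2 candidate features")
  y <- as.integer(y)
  foldid <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      ids <- sample(which(y == cls))
      f[ids] <- rep_len(seq_len(nfolds), length(ids))
    }
    f
  })
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", foldid = foldid,
                          type.measure = "deviance", standardize = TRUE)
  lambda <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  beta <- as.matrix(coef(cv, s = lambda))[-1, 1]
  sel <- names(beta)[beta != 0]
  structure(sel, lambda = lambda, empty = length(sel) == 0)
}

#' Build the twelve-model suite
#'
#' M1 = clinical reference (histology + clinical T-stage); M2 = radiomic
#' reference (selected radiomic features); M3 = M1 union M2; M4-M6 add HER2;
#' M7-M9 add CD44; M10-M12 add both markers. Marker models are fit on the
#' complete cases for the markers involved (missing marker status excluded,
#' never imputed).
#'
#' @param data data.frame containing the clinical columns, marker columns
#'   and radiomic features.
#' @param y binary outcome aligned with `data`.
#' @param clinical_terms covariates of M1.
#' @param radiomic_terms covariates of M2 (e.g. the LASSO-selected set).
#' @param marker_terms named character vector of length 2: the HER2 and CD44
#'   columns.
#' @return list of class `model_suite` with elements `M1`..`M12`, each
#'   carrying `spec` (covariates, n, complete-case ids) and `fit`.
#' @export
build_model_suite <- function(data, y,
                              clinical_terms = c("histology_squamous",
                                                 "ct_t34a"),
                              radiomic_terms,
                              marker_terms = c(her2 = "her2", cd44 = "cd44")) {
  abort_if(length(marker_terms) != 2, "need exactly 2 marker terms")
  base_sets <- list(M1 = clinical_terms, M2 = radiomic_terms,
                    M3 = union(clinical_terms, radiomic_terms))
  marker_sets <- list(character(0), marker_terms[1], marker_terms[2],
                      unname(marker_terms))
  suite <- list()
  idx <- 0
  for (mk in marker_sets) {
    for (b in names(base_sets)) {
      idx <- idx + 1
      name <- paste0("M", idx)
      covs <- c(base_sets[[b]], unname(mk))
      keep <- rep(TRUE, nrow(data))
      for (m in mk) keep <- keep & !is.na(data[[m]])
      sub <- data[keep, covs, drop = FALSE]
      for (m in mk) sub[[m]] <- as.numeric(sub[[m]] == "positive" |
                                             sub[[m]] == 1 | sub[[m]] == TRUE)
      fit <- fit_logistic(sub, y[keep])
      suite[[name]] <- list(name = name, covariates = covs,
                            marker_terms = unname(mk), n = sum(keep),
                            rows = which(keep), fit = fit)
    }
  }
  structure(suite, class = "model_suite")
}

#' @export
print.model_suite <- function(x, ...) {
  for (m in x) {
    cat(sprintf("%-4s n=%3d k=%d AIC=%7.2f  [%s]\n", m$name, m$n, m$fit$k,
                m$fit$aic, paste(m$covariates, collapse = ", ")))
  }
  invisible(x)
}
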