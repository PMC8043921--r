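# Biomarker handling: HER2 dichotomization (immunohistochemistry score with
# FISH resolution of equivocal cases), 2x2 diagnostic metrics with exact
# binomial confidence intervals, the two-sided Fisher exact test, and
# patient-cluster / covariate association tests.

#' Dichotomize HER2 from IHC score and FISH result
#'
#' Score 0 is negative and 3+ positive; the equivocal scores 1+ and 2+ are
#' resolved by fluorescence in situ hybridization (amplified = positive), and
#' are missing when no FISH result is available.
#'
#' @param ihc_score character vector in `{"0", "1+", "2+", "3+"}`.
#' @param fish character vector in `{"amplified", "not_amplified",
#'   "unavailable"}`.
#' @return character vector in `{"negative", "positive", "missing"}`.
#' @export
dichotomize_her2 <- function(ihc_score,
                             fish = rep("unavailable", length(ihc_score))) {
  abort_if(!all(ihc_score %in% c("0", "1+", "2+", "3+")),
           "invalid HER2 IHC score; expected 0, 1+, 2+ or 3+")
  abort_if(!all(fish %in% c("amplified", "not_amplified", "unavailable")),
           "invalid FISH level")
  out <- ifelse(ihc_score == "0", "negative",
         ifelse(ihc_score == "3+", "positive",
         ifelse(fish == "amplified", "positive",
         ifelse(fish == "not_amplified", "negative", "missing"))))
  out
}

#' Diagnostic metrics of a 2x2 table
#'
#' Sensitivity, specificity, positive and negative predictive value with
#' exact (Clopper-Pearson) binomial confidence intervals. The table is
#' oriented rows = test (positive first), columns = outcome (positive
#' first). Metrics with an empty denominator are `NA`-flagged.
#'
#' @param t 2x2 integer matrix.
#' @param conf_level confidence level for the exact intervals.
#' @return data.frame `metric`, `estimate`, `lower`, `upper`, `x`, `n`.
#' @export
diagnostic_metrics <- function(t, conf_level = 0.95) {
  abort_if(!all(dim(t) == c(2, 2)) || any(t < 0) || sum(t) == 0,
           "need a nonnegative 2x2 table with positive total")
  tp <- t[1, 1]; fp <- t[1, 2]; fn <- t[2, 1]; tn <- t[2, 2]
  one <- function(metric, x, n) {
    if (n == 0) {
      return(data.frame(metric = metric, estimate = NA_real_,
                        lower = NA_real_, upper = NA_real_, x = x, n = n))
    }
    ci <- binom.test(x, n, conf.level = conf_level)$conf.int
    data.frame(metric = metric, estimate = x / n, lower = ci[1],
               upper = ci[2], x = x, n = n)
  }
  rbind(one("sensitivity", tp, tp + fn),
        one("specificity", tn, tn + fp),
        one("ppv", tp, tp + fp),
        one("npv", tn, tn + fn))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric p value by the point-probability method: the sum of
#' the probabilities of all tables (with the observed margins) whose point
#' probability does not exceed the observed one, within a relative tolerance
#' of 1e-7. This is the convention of mainstream statistical software.
#'
#' @param t 2x2 integer matrix.
#' @return two-sided p value.
#' @export
fisher_exact_2x2 <- function(t) {
  abort_if(!all(dim(t) == c(2, 2)) || any(t < 0) || sum(t) == 0,
           "need a nonnegative 2x2 table with positive total")
  m <- t[1, 1] + t[1, 2]   # row 1 total
  n <- t[2, 1] + t[2, 2]   # row 2 total
  k <- t[1, 1] + t[2, 1]   # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(t[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Association between patient clusters and a categorical covariate
#'
#' Contingency chi-square test; switches to the exact test when more than
#' 20% of expected cell counts fall below 5 (flagged in `method`).
#'
#' @param clusters cluster labels (>= 2 distinct values).
#' @param covariate categorical covariate aligned with `clusters`; `NA`
#'   entries are excluded.
#' @return list `p`, `statistic` (chi-square, `NA` for the exact branch),
#'   `method`, `table`.
#' @export
cluster_covariate_association <- function(clusters, covariate) {
  keep <- !is.na(covariate) & !is.na(clusters)
  tab <- table(cluster = clusters[keep], covariate = covariate[keep])
  abort_if(nrow(tab) < 2, "need at least 2 clusters")
  abort_if(ncol(tab) < 2, "covariate is degenerate (single level)")
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  if (mean(cs$expected < 5) > 0.2) {
    p <- fisher.test(tab, simulate.p.value = nrow(tab) * ncol(tab) > 2e5)$p.value
    list(p = p, statistic = NA_real_,
         method = "fisher_exact_low_expected_counts", table = tab)
  } else {
    list(p = cs$p.value, statistic = unname(cs$statistic),
         method = "chi_square", table = tab)
  }
}
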