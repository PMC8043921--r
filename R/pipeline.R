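# End-to-end orchestration: simulate (or load) a cohort, optionally extract
# image features, reduce the feature space, build the twelve-model suite and
# validate every model, producing a self-contained machine-readable report.

#' Pipeline run configuration
#'
#' A single master seed fans out to per-stage seeds through a fixed counter
#' scheme (`child_seed`), so any stage can be rerun in isolation.
#'
#' @param cohort a [cohort_spec()] describing the simulated cohort (or `NULL`
#'   when `features`/`labels` are supplied directly to [run_pipeline()]).
#' @param cut_fraction dendrogram cut fraction for feature clustering.
#' @param screen_alpha univariable screening level (default 0.2).
#' @param lasso_rule `"min"` or `"1se"` penalty choice.
#' @param B bootstrap repetitions per model.
#' @param refit_policy bootstrap refit policy, `"fixed"` or `"pipeline"`.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(), cut_fraction = 0.6,
                            screen_alpha = 0.2, lasso_rule = "min",
                            B = 1000, refit_policy = "fixed", seed = 1L) {
  structure(list(cohort = cohort, cut_fraction = cut_fraction,
                 screen_alpha = screen_alpha, lasso_rule = lasso_rule,
                 B = as.integer(B), refit_policy = refit_policy,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full clinico-radiomic modelling pipeline
#'
#' Stages, in order: simulate the cohort (unless `features`/`labels` are
#' given), cluster the radiomic features and select screened representatives,
#' LASSO-select the radiomic model covariates (falling back to the best
#' screened representative when the selection is empty), build the
#' twelve-model suite, and bootstrap-validate every model. Any stage error
#' aborts with the stage name.
#'
#' @param config a [pipeline_config()].
#' @param features optional patients x covariates data.frame (clinical
#'   columns, markers and radiomic features) overriding simulation.
#' @param labels optional binary outcome aligned with `features`.
#' @param out optional path; when given, the report is written as JSON.
#' @return list of class `run_report`: `models` (per-model rows: AIC and the
#'   six measures, apparent and corrected), `clusters`, `representatives`,
#'   `selected_radiomic`, `marker_stats`, `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), features = NULL,
                         labels = NULL, out = NULL) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  if (is.null(features)) {
    cohort <- stage("simulate", generate_cohort(config$cohort))
    features <- cohort$features
    labels <- cohort$labels
  } else {
    abort_if(is.null(labels), "`labels` must accompany `features`")
    cohort <- NULL
  }
  clinical_cols <- intersect(c("histology_squamous", "ct_t34a", "cn_n23"),
                             names(features))
  marker_cols <- intersect(c("her2", "cd44"), names(features))
  radiomic_cols <- setdiff(names(features), c(clinical_cols, marker_cols))
  rad <- features[, radiomic_cols, drop = FALSE]

  red <- stage("reduce", {
    d <- spearman_distance(rad)
    cl <- cluster_features(d, config$cut_fraction)
    reps <- select_representatives(cl, rad, labels,
                                   threshold = config$screen_alpha)
    list(clusters = cl, reps = reps)
  })
  kept <- red$reps$feature[red$reps$kept]

  selected <- stage("select", {
    if (length(kept) >= 2) {
      sel <- lasso_select(features[, kept, drop = FALSE], labels,
                          seed = child_seed(config$seed, 11L),
                          rule = config$lasso_rule)
      if (attr(sel, "empty")) {
        best <- red$reps[red$reps$kept, ]
        sel <- best$feature[which.min(best$p)]
      }
      as.character(sel)
    } else kept
  })
  abort_if(length(selected) == 0,
           "no radiomic feature survived screening; cannot build M2")

  suite <- stage("fit", build_model_suite(
    features, labels, clinical_terms = clinical_cols,
    radiomic_terms = selected,
    marker_terms = c(her2 = "her2", cd44 = "cd44")))

  reports <- stage("validate", {
    lapply(suite, function(m) {
      bootstrap_validate(features[m$rows, , drop = FALSE],
                         labels[m$rows], m$covariates, B = config$B,
                         seed = child_seed(config$seed,
                                           20L + as.integer(sub("M", "",
                                                                m$name))),
                         refit_policy = "fixed")
    })
  })

  marker_stats <- stage("markers", {
    lapply(marker_cols, function(mc) {
      x <- features[[mc]]
      keep <- !is.na(x)
      s <- univariable_lrt(as.numeric(x[keep] == "positive" | x[keep] == 1),
                           labels[keep])
      list(marker = mc, lrt_p = s$p, n = sum(keep))
    })
  })

  rows <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, n = r$n, aic = r$aic,
               t(r$measures["apparent", ]),
               t(`names<-`(r$measures["corrected", ],
                           paste0("corrected_",
                                  colnames(r$measures)))),
               check.names = FALSE, row.names = NULL)
  }))
  report <- structure(list(
    models = rows,
    clusters = list(n_feature_clusters = red$clusters$n_clusters,
                    cut_height = red$clusters$cut_height),
    representatives = red$reps,
    selected_radiomic = selected,
    marker_stats = marker_stats,
    provenance = list(config_hash = config_hash(unclass(config)),
                      seed = config$seed, B = config$B,
                      r_version = as.character(getRversion()))),
    class = "run_report")
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         force = TRUE, pretty = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d models, %d feature clusters, radiomic terms: %s\n",
              nrow(x$models), x$clusters$n_feature_clusters,
              paste(x$selected_radiomic, collapse = ", ")))
  print(x$models[, c("model", "n", "aic", "corrected_r2", "corrected_auc")],
        digits = 3)
  invisible(x)
}
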