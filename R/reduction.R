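# Feature-space reduction: Spearman-correlation distance, average-linkage
# agglomerative clustering cut at a fraction of the maximum linkage height,
# and per-cluster representative selection by univariable likelihood-ratio
# screening.

#' Spearman correlation distance between feature columns
#'
#' d_ij = 1 - |rho_ij| by default (redundancy is sign-agnostic); the signed
#' variant 1 - rho is available. Constant columns carry no rank information
#' and are excluded with a warning.
#'
#' @param features data.frame or matrix, patients x features.
#' @param absolute use |rho| (default) rather than rho.
#' @return object of class `dist` over the retained features.
#' @export
spearman_distance <- function(features, absolute = TRUE) {
  X <- as.matrix(features)
  abort_if(nrow(X) < 2, "need at least 2 patients")
  const <- apply(X, 2, function(v) length(unique(v[!is.na(v)])) <= 1)
  if (all(const)) stop("all feature columns are constant", call. = FALSE)
  if (any(const)) {
    warning("excluding constant feature(s): ",
            paste(colnames(X)[const], collapse = ", "), call. = FALSE)
    X <- X[, !const, drop = FALSE]
  }
  rho <- cor(X, method = "spearman", use = "pairwise.complete.obs")
  d <- if (absolute) 1 - abs(rho) else 1 - rho
  diag(d) <- 0
  as.dist(d)
}

#' Cluster features by average-linkage agglomeration
#'
#' Builds the average-linkage dendrogram on a correlation distance and cuts
#' it at `cut_fraction` of the maximum linkage height; clusters are the
#' subtrees entirely below the cut.
#'
#' @param d a `dist` from [spearman_distance()].
#' @param cut_fraction fraction f of the maximum linkage height, 0 < f <= 1
#'   (f = 1 merges everything into one cluster); the study convention is 0.6.
#' @return list of class `feature_dendrogram`: `tree` (hclust), `cut_height`,
#'   `assignment` (named integer cluster ids), `n_clusters`.
#' @export
cluster_features <- function(d, cut_fraction = 0.6) {
  abort_if(!inherits(d, "dist"), "`d` must be a dist object")
  abort_if(cut_fraction <= 0 || cut_fraction > 1,
           "`cut_fraction` must be in (0, 1]")
  tree <- hclust(d, method = "average")
  h_max <- max(tree$height)
  cut_h <- cut_fraction * h_max
  assignment <- cutree(tree, h = cut_h)
  structure(list(tree = tree, cut_height = cut_h, cut_fraction = cut_fraction,
                 assignment = assignment,
                 n_clusters = length(unique(assignment))),
            class = "feature_dendrogram")
}

#' Univariable likelihood-ratio p value of one feature
#'
#' Binomial GLM of the outcome on the single feature against the
#' intercept-only model; two-sided 1-df chi-square on the deviance drop.
#' Perfect separation is caught (guarded deviance) and flagged.
#'
#' @param x numeric or binary covariate.
#' @param y binary outcome (0/1 or logical), both classes present.
#' @return list `p`, `deviance_drop`, `separation` (logical).
#' @export
univariable_lrt <- function(x, y) {
  y <- as.integer(y)
  abort_if(length(unique(y)) < 2, "outcome has a single class")
  sep <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ x, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  drop <- max(fit$null.deviance - fit$deviance, 0)
  list(p = pchisq(drop, df = 1, lower.tail = FALSE),
       deviance_drop = drop, separation = sep)
}

#' Select one representative feature per cluster by minimum LRT p
#'
#' Within each cluster the feature with the smallest univariable
#' likelihood-ratio p value is the representative (ties broken by canonical
#' feature-name order); representatives with p >= `threshold` are dropped
#' from the selected set (but still reported).
#'
#' @param clusters a [cluster_features()] result.
#' @param features the feature table the clustering was computed on.
#' @param y binary outcome.
#' @param threshold screening level, default 0.2.
#' @return data.frame with one row per cluster: `cluster`, `feature`, `p`,
#'   `separation`, `kept`.
#' @export
select_representatives <- function(clusters, features, y, threshold = 0.2) {
  stopifnot(inherits(clusters, "feature_dendrogram"))
  assignment <- clusters$assignment
  out <- lapply(sort(unique(assignment)), function(k) {
    members <- sort(names(assignment)[assignment == k])
    stats <- lapply(members, function(f)
      univariable_lrt(features[[f]], y))
    ps <- vapply(stats, `[[`, 0, "p")
    best <- which.min(ps)  # first minimum = lexicographically first on ties
    data.frame(cluster = k, feature = members[best], p = ps[best],
               separation = stats[[best]]$separation,
               kept = ps[best] < threshold, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cluster patients on the Z-scored feature table
#'
#' Same machinery as [cluster_features()] applied to the transposed,
#' per-feature Z-scored table, as used for patient-cluster heatmaps.
#'
#' @param features patients x features table.
#' @param cut_fraction dendrogram cut fraction.
#' @return a `feature_dendrogram` over patients.
#' @export
cluster_patients <- function(features, cut_fraction = 0.6) {
  X <- as.matrix(features)
  keep <- apply(X, 2, function(v) sd(v) > 0)
  Z <- scale(X[, keep, drop = FALSE])
  rownames(Z) <- rownames(X) %||% paste0("p", seq_len(nrow(X)))
  cluster_features(spearman_distance(t(Z)), cut_fraction)
}
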