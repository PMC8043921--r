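# Texture feature families over a discretized ROI: gray-level co-occurrence
# (GLCM), run-length (GLRLM), size-zone (GLSZM) and neighborhood gray-tone
# difference (NGTDM) matrices. Directional matrices use the 13 unique 3D
# directions at Chebyshev distance 1; directional features are averaged over
# directions by default, with a merged-matrix variant available.

xlog2x <- function(p) ifelse(p > 0, p * log2(p), 0)

glcm_matrix <- function(levels, ng, d) {
  b <- shift_array(levels, d)
  sel <- !is.na(levels) & !is.na(b)
  if (!any(sel)) return(matrix(0, ng, ng))
  a <- levels[sel]
  bb <- b[sel]
  counts <- tabulate((a - 1L) * ng + bb, nbins = ng * ng)
  C <- matrix(counts, ng, ng, byrow = TRUE)
  C + t(C)  # symmetric co-occurrence
}

glcm_feature_values <- function(P) {
  ng <- nrow(P)
  tot <- sum(P)
  if (tot == 0) {
    v <- rep(NA_real_, length(glcm_feature_names))
    names(v) <- glcm_feature_names
    return(v)
  }
  P <- P / tot
  I <- row(P)
  J <- col(P)
  px <- rowSums(P)  # symmetric: py = px
  mu <- sum(I * P)
  kd <- 0:(ng - 1)
  p_dm <- vapply(kd, function(k) sum(P[abs(I - J) == k]), 0)
  ks <- 2:(2 * ng)
  p_sp <- vapply(ks, function(k) sum(P[I + J == k]), 0)
  da <- sum(kd * p_dm)
  sa <- sum(ks * p_sp)
  hxy <- -sum(xlog2x(P))
  pxy <- px[I] * px[J]
  hxy1 <- -sum(P[pxy > 0] * log2(pxy[pxy > 0]))
  hxy2 <- -sum(xlog2x(pxy))
  hx <- -sum(xlog2x(px))
  mu_x <- sum(seq_len(ng) * px)
  var_x <- sum((seq_len(ng) - mu_x)^2 * px)
  autoc <- sum(I * J * P)
  offd <- I != J
  c(
    joint_max = max(P),
    joint_average = mu,
    joint_variance = sum((I - mu)^2 * P),
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum((kd - da)^2 * p_dm),
    difference_entropy = -sum(xlog2x(p_dm)),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * p_sp),
    sum_entropy = -sum(xlog2x(p_sp)),
    angular_second_moment = sum(P^2),
    contrast = sum((I - J)^2 * P),
    dissimilarity = sum(abs(I - J) * P),
    inverse_difference = sum(P / (1 + abs(I - J))),
    inverse_difference_norm = sum(P / (1 + abs(I - J) / ng)),
    inverse_difference_moment = sum(P / (1 + (I - J)^2)),
    inverse_difference_moment_norm = sum(P / (1 + (I - J)^2 / ng^2)),
    inverse_variance = sum(P[offd] / (I[offd] - J[offd])^2),
    correlation = if (var_x > 0) (autoc - mu_x^2) / var_x else NA_real_,
    autocorrelation = autoc,
    cluster_tendency = sum((I + J - 2 * mu_x)^2 * P),
    cluster_shade = sum((I + J - 2 * mu_x)^3 * P),
    cluster_prominence = sum((I + J - 2 * mu_x)^4 * P),
    information_correlation_1 = if (hx > 0) (hxy - hxy1) / hx else NA_real_,
    information_correlation_2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  )
}

glcm_feature_names <- c(
  "joint_max", "joint_average", "joint_variance", "joint_entropy",
  "difference_average", "difference_variance", "difference_entropy",
  "sum_average", "sum_variance", "sum_entropy", "angular_second_moment",
  "contrast", "dissimilarity", "inverse_difference",
  "inverse_difference_norm", "inverse_difference_moment",
  "inverse_difference_moment_norm", "inverse_variance", "correlation",
  "autocorrelation", "cluster_tendency", "cluster_shade",
  "cluster_prominence", "information_correlation_1",
  "information_correlation_2")

#' Gray-level co-occurrence features (25)
#'
#' Symmetric co-occurrence over the 13 unique 3D directions at distance 1.
#' By default each feature is computed per direction and averaged; the
#' `"merge"` aggregation pools the 13 matrices before computing features.
#' With a single gray level, distance-weighted features are 0 and
#' margin-dependent features (correlation, information correlations) are
#' undefined and returned as `NA` (flagged).
#'
#' @param droi a [discretize()]d ROI.
#' @param aggregation `"average"` or `"merge"`.
#' @return named numeric vector of 25 features with attribute `flags`.
#' @export
glcm_features <- function(droi, aggregation = c("average", "merge")) {
  stopifnot(inherits(droi, "discretized_roi"))
  aggregation <- match.arg(aggregation)
  dirs <- unique_directions3()
  mats <- lapply(seq_len(nrow(dirs)), function(i)
    glcm_matrix(droi$levels, droi$ng, dirs[i, ]))
  used <- vapply(mats, sum, 0) > 0
  flags <- character(0)
  if (!all(used)) flags <- c(flags, "directions_without_pairs_dropped")
  if (!any(used)) {
    v <- rep(NA_real_, 25)
    names(v) <- glcm_feature_names
    attr(v, "flags") <- c(flags, "no_voxel_pairs")
    return(v)
  }
  if (aggregation == "merge") {
    v <- glcm_feature_values(Reduce(`+`, mats[used]))
  } else {
    fv <- vapply(mats[used], glcm_feature_values,
                 numeric(length(glcm_feature_names)))
    v <- rowMeans(fv)
  }
  if (anyNA(v)) flags <- c(flags, paste0("undefined:",
                                         names(v)[is.na(v)]))
  attr(v, "flags") <- flags
  v
}

# enumerate maximal lattice lines along direction d and return, per line, the
# linear indices in walking order
lattice_lines <- function(dims, d) {
  inb <- array(TRUE, dim = dims)
  prev <- shift_array(inb, -d)  # prev[x] = TRUE iff x - d is inside the grid
  starts <- which(is.na(prev))
  step <- d[1] + d[2] * dims[1] + d[3] * dims[1] * dims[2]
  ijk <- arrayInd(starts, dims)
  tmax <- rep(Inf, length(starts))
  for (ax in 1:3) {
    if (d[ax] > 0) tmax <- pmin(tmax, dims[ax] - ijk[, ax])
    if (d[ax] < 0) tmax <- pmin(tmax, ijk[, ax] - 1)
  }
  lapply(seq_along(starts), function(i)
    starts[i] + step * (0:tmax[i]))
}

glrlm_matrix <- function(levels, ng, d) {
  dims <- dim(levels)
  maxlen <- max(dims)
  R <- matrix(0, ng, maxlen)
  for (line in lattice_lines(dims, d)) {
    v <- levels[line]
    v[is.na(v)] <- 0L  # out-of-mask voxels break runs
    r <- rle(v)
    keep <- r$values > 0
    if (any(keep)) {
      idx <- (r$lengths[keep] - 1L) * ng + r$values[keep]
      counts <- tabulate(idx, nbins = ng * maxlen)
      R <- R + matrix(counts, ng, maxlen)
    }
  }
  R
}

rl_feature_values <- function(R, nv, zone = FALSE) {
  ns <- sum(R)
  nms <- rl_feature_names(zone)
  if (ns == 0) {
    v <- rep(NA_real_, length(nms))
    names(v) <- nms
    return(v)
  }
  ng <- nrow(R)
  i <- row(R)
  j <- col(R)
  p <- R / ns
  ri <- rowSums(R)
  rj <- colSums(R)
  mu_i <- sum(seq_len(ng) * ri / ns)
  mu_j <- sum(seq_len(ncol(R)) * rj / ns)
  v <- c(
    sum(R / j^2) / ns,                     # short run / small zone emphasis
    sum(R * j^2) / ns,                     # long run / large zone emphasis
    sum(R / i^2) / ns,                     # low gray-level emphasis
    sum(R * i^2) / ns,                     # high gray-level emphasis
    sum(R / (i^2 * j^2)) / ns,             # short+low
    sum(R * i^2 / j^2) / ns,               # short+high
    sum(R * j^2 / i^2) / ns,               # long+low
    sum(R * i^2 * j^2) / ns,               # long+high
    sum(ri^2) / ns,                        # gray-level non-uniformity
    sum(ri^2) / ns^2,                      # ... normalized
    sum(rj^2) / ns,                        # run/zone-length non-uniformity
    sum(rj^2) / ns^2,                      # ... normalized
    ns / nv,                               # run/zone percentage
    sum(p * (i - mu_i)^2),                 # gray-level variance
    sum(p * (j - mu_j)^2),                 # run-length / zone-size variance
    -sum(xlog2x(p))                        # run/zone entropy
  )
  names(v) <- nms
  v
}

rl_feature_names <- function(zone = FALSE) {
  if (zone) {
    c("small_zone_emphasis", "large_zone_emphasis",
      "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
      "small_zone_low_gray_level_emphasis",
      "small_zone_high_gray_level_emphasis",
      "large_zone_low_gray_level_emphasis",
      "large_zone_high_gray_level_emphasis",
      "gray_level_nonuniformity", "gray_level_nonuniformity_norm",
      "zone_size_nonuniformity", "zone_size_nonuniformity_norm",
      "zone_percentage", "gray_level_variance", "zone_size_variance",
      "zone_size_entropy")
  } else {
    c("short_run_emphasis", "long_run_emphasis",
      "low_gray_level_run_emphasis", "high_gray_level_run_emphasis",
      "short_run_low_gray_level_emphasis",
      "short_run_high_gray_level_emphasis",
      "long_run_low_gray_level_emphasis",
      "long_run_high_gray_level_emphasis",
      "gray_level_nonuniformity", "gray_level_nonuniformity_norm",
      "run_length_nonuniformity", "run_length_nonuniformity_norm",
      "run_percentage", "gray_level_variance", "run_length_variance",
      "run_entropy")
  }
}

#' Gray-level run-length features (16)
#'
#' Runs of equal gray level along each of the 13 unique 3D directions;
#' out-of-mask voxels break runs. Features are averaged over directions by
#' default (merged-matrix variant via `aggregation = "merge"`).
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features with attribute `flags`.
#' @export
glrlm_features <- function(droi, aggregation = c("average", "merge")) {
  stopifnot(inherits(droi, "discretized_roi"))
  aggregation <- match.arg(aggregation)
  nv <- sum(!is.na(droi$levels))
  dirs <- unique_directions3()
  mats <- lapply(seq_len(nrow(dirs)), function(i)
    glrlm_matrix(droi$levels, droi$ng, dirs[i, ]))
  if (aggregation == "merge") {
    v <- rl_feature_values(Reduce(`+`, mats), nv * nrow(dirs))
  } else {
    fv <- vapply(mats, rl_feature_values, numeric(16), nv = nv)
    v <- rowMeans(fv)
  }
  attr(v, "flags") <- character(0)
  v
}

#' Gray-level size-zone features (16)
#'
#' Zones are 26-connected components of equal gray level within the mask;
#' a single zone matrix is computed for the whole volume.
#'
#' @param droi a [discretize()]d ROI.
#' @return named numeric vector of 16 features with attribute `flags`.
#' @export
glszm_features <- function(droi) {
  stopifnot(inherits(droi, "discretized_roi"))
  levels <- droi$levels
  dims <- dim(levels)
  ids <- which(!is.na(levels))
  nv <- length(ids)
  pos <- match(seq_len(prod(dims)), ids)  # linear index -> vertex id
  dirs <- unique_directions3()
  e_from <- integer(0)
  e_to <- integer(0)
  for (i in seq_len(nrow(dirs))) {
    d <- dirs[i, ]
    b <- shift_array(levels, d)
    sel <- which(!is.na(levels) & !is.na(b) & levels == b)
    if (length(sel)) {
      step <- d[1] + d[2] * dims[1] + d[3] * dims[1] * dims[2]
      e_from <- c(e_from, pos[sel])
      e_to <- c(e_to, pos[sel + step])
    }
  }
  g <- igraph::make_empty_graph(n = nv, directed = FALSE)
  if (length(e_from)) {
    g <- igraph::add_edges(g, rbind(e_from, e_to))
  }
  comp <- igraph::components(g)
  zone_size <- as.integer(comp$csize)
  first_of <- match(seq_len(comp$no), comp$membership)
  zone_level <- levels[ids[first_of]]
  ng <- droi$ng
  maxs <- max(zone_size)
  S <- matrix(tabulate((zone_size - 1L) * ng + zone_level, nbins = ng * maxs),
              ng, maxs)
  v <- rl_feature_values(S, nv, zone = TRUE)
  attr(v, "flags") <- character(0)
  v
}

#' Neighborhood gray-tone difference features (5)
#'
#' For each in-mask voxel with at least one in-mask 26-neighbor, the absolute
#' difference between its gray level and the mean level of those neighbors
#' is accumulated per level. Coarseness uses a 1e-12 guard on its reciprocal
#' and is flagged when the guard caps the value; busyness/contrast/strength
#' are `NA`-flagged when only one gray level is present.
#'
#' @param droi a [discretize()]d ROI.
#' @param eps reciprocal guard for coarseness.
#' @return named numeric vector of 5 features with attribute `flags`.
#' @export
ngtdm_features <- function(droi, eps = 1e-12) {
  stopifnot(inherits(droi, "discretized_roi"))
  levels <- droi$levels
  dims <- dim(levels)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  nsum <- array(0, dim = dims)
  ncnt <- array(0L, dim = dims)
  for (i in seq_len(nrow(offs))) {
    b <- shift_array(levels, as.numeric(offs[i, ]))
    has <- !is.na(b)
    nsum[has] <- nsum[has] + b[has]
    ncnt <- ncnt + as.integer(has)
  }
  valid <- !is.na(levels) & ncnt > 0
  nvv <- sum(valid)
  ng <- droi$ng
  abar <- nsum[valid] / ncnt[valid]
  lev <- levels[valid]
  diffs <- abs(lev - abar)
  n_i <- tabulate(lev, nbins = ng)
  s_i <- vapply(seq_len(ng), function(i) sum(diffs[lev == i]), 0)
  p_i <- n_i / nvv
  present <- which(p_i > 0)
  ngp <- length(present)
  flags <- character(0)
  denom_coarse <- sum(p_i * s_i)
  coarseness <- 1 / (eps + denom_coarse)
  if (denom_coarse < eps) flags <- c(flags, "coarseness_capped")
  if (ngp > 1) {
    pi_p <- p_i[present]
    si_p <- s_i[present]
    lv <- present
    D2 <- outer(lv, lv, function(a, b) (a - b)^2)
    pp <- outer(pi_p, pi_p)
    contrast <- (sum(pp * D2) / (ngp * (ngp - 1))) * (sum(si_p) / nvv)
    busy_den <- sum(abs(outer(lv * pi_p, lv * pi_p, `-`)))
    busyness <- if (busy_den > 0) sum(pi_p * si_p) / busy_den else NA_real_
    Dabs <- outer(lv, lv, function(a, b) abs(a - b))
    psi <- pi_p * si_p
    complexity <- sum(Dabs * (outer(psi, psi, `+`)) / outer(pi_p, pi_p, `+`)) /
      nvv
    strength <- if (sum(si_p) > 0)
      sum(outer(pi_p, pi_p, `+`) * D2) / sum(si_p) else 0
  } else {
    contrast <- 0
    busyness <- NA_real_
    complexity <- 0
    strength <- 0
    flags <- c(flags, "single_gray_level")
  }
  v <- c(coarseness = coarseness, contrast = contrast, busyness = busyness,
         complexity = complexity, strength = strength)
  attr(v, "flags") <- flags
  v
}
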