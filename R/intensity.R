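# Intensity-statistical features (including the spatial autocorrelation
# statistics Moran's I and Geary's C with inverse-distance weights) and the
# local intensity (SUVpeak) features.

stat_feature_names <- c(
  "mean", "median", "minimum", "maximum", "p10", "p90", "variance",
  "skewness", "kurtosis", "energy", "rms", "range", "iqr",
  "mean_absolute_deviation", "median_absolute_deviation",
  "coefficient_of_variation", "morans_i", "gearys_c")

#' Intensity-statistical features (18)
#'
#' First-order statistics of the in-mask SUV distribution plus the two
#' spatial autocorrelation statistics, computed with inverse Euclidean
#' distance weights w_ij = 1/d_ij (mm) between in-mask voxel centres:
#' Moran's I = (N / sum w_ij) * sum w_ij z_i z_j / sum z_i^2 and Geary's C =
#' ((N - 1) / (2 sum w_ij)) * sum w_ij (x_i - x_j)^2 / sum z_i^2, with z the
#' mean-centred intensities. Kurtosis is excess kurtosis. With zero in-mask
#' variance the autocorrelation statistics are undefined and `NA`-flagged.
#'
#' For ROIs larger than `max_autocorr_voxels` the autocorrelation statistics
#' are computed on a deterministic intensity-stratified systematic subsample
#' of that size (flagged in the result).
#'
#' @param vol a [pet_volume()].
#' @param mask a [roi_mask()] on the same grid.
#' @param max_autocorr_voxels exact-computation cap for Moran/Geary.
#' @return named numeric vector of 18 features with attribute `flags`.
#' @export
intensity_statistics <- function(vol, mask, max_autocorr_voxels = 20000L) {
  stopifnot(inherits(vol, "pet_volume"), inherits(mask, "roi_mask"))
  check_same_grid(vol, mask)
  x <- vol$values[mask$values]
  n <- length(x)
  mu <- mean(x)
  v <- if (n > 1) sum((x - mu)^2) / n else 0  # population variance
  sk <- if (v > 0) mean((x - mu)^3) / v^1.5 else NA_real_
  ku <- if (v > 0) mean((x - mu)^4) / v^2 - 3 else NA_real_
  flags <- character(0)
  idx <- which(mask$values, arr.ind = TRUE)
  coords <- sweep(idx - 0.5, 2, mask$spacing, `*`)
  if (n > max_autocorr_voxels) {
    # deterministic stratified systematic subsample: order by intensity,
    # take every k-th voxel
    ord <- order(x, seq_along(x))
    take <- ord[round(seq(1, n, length.out = max_autocorr_voxels))]
    ac <- spatial_autocorrelation(x[take], coords[take, , drop = FALSE])
    flags <- c(flags, sprintf("autocorrelation_subsampled_%d_of_%d",
                              length(take), n))
  } else {
    ac <- spatial_autocorrelation(x, coords)
  }
  if (anyNA(ac)) flags <- c(flags, "autocorrelation_undefined_zero_variance")
  q <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  vals <- c(
    mean = mu, median = q[3], minimum = min(x), maximum = max(x),
    p10 = q[1], p90 = q[5], variance = v, skewness = sk, kurtosis = ku,
    energy = sum(x^2), rms = sqrt(mean(x^2)), range = max(x) - min(x),
    iqr = q[4] - q[2], mean_absolute_deviation = mean(abs(x - mu)),
    median_absolute_deviation = median(abs(x - q[3])),
    coefficient_of_variation = if (mu != 0) sqrt(v) / mu else NA_real_,
    morans_i = ac[["morans_i"]], gearys_c = ac[["gearys_c"]]
  )
  if (is.na(sk) || is.na(ku)) flags <- c(flags, "zero_variance_moments")
  attr(vals, "flags") <- flags
  vals
}

# chunked exact computation of Moran's I and Geary's C with w = 1/distance
spatial_autocorrelation <- function(x, coords, chunk = 256L) {
  n <- length(x)
  if (n < 2) return(c(morans_i = NA_real_, gearys_c = NA_real_))
  z <- x - mean(x)
  sz2 <- sum(z^2)
  if (sz2 == 0) return(c(morans_i = NA_real_, gearys_c = NA_real_))
  s0 <- 0
  num_m <- 0
  num_g <- 0
  for (lo in seq(1, n, by = chunk)) {
    hi <- min(lo + chunk - 1, n)
    ii <- lo:hi
    d2 <- outer(coords[ii, 1], coords[, 1], `-`)^2 +
      outer(coords[ii, 2], coords[, 2], `-`)^2 +
      outer(coords[ii, 3], coords[, 3], `-`)^2
    w <- 1 / sqrt(d2)
    w[!is.finite(w)] <- 0  # self pairs (d = 0)
    s0 <- s0 + sum(w)
    num_m <- num_m + as.numeric(z[ii] %*% w %*% z)
    num_g <- num_g + sum(w * outer(x[ii], x, `-`)^2)
  }
  c(morans_i = (n / s0) * num_m / sz2,
    gearys_c = ((n - 1) / (2 * s0)) * num_g / sz2)
}

#' Local intensity features: SUVpeak (2)
#'
#' `peak_global`: maximum, over all in-mask voxel centres, of the mean SUV
#' within a 1 cm3 sphere (radius 6.204 mm) centred on the voxel; the sphere
#' mean includes every image voxel whose centre lies within the radius
#' (background included), voxels outside the grid excluded. `peak_local`:
#' the sphere mean at the global maximum-SUV in-mask voxel (maximum over
#' tied voxels).
#'
#' @param vol a [pet_volume()].
#' @param mask a [roi_mask()] on the same grid.
#' @param radius_mm sphere radius; default gives a 1 cm3 sphere.
#' @return named numeric vector `c(peak_global, peak_local)`.
#' @export
local_intensity_features <- function(vol, mask,
                                     radius_mm = (3 / (4 * pi))^(1 / 3) * 10) {
  stopifnot(inherits(vol, "pet_volume"), inherits(mask, "roi_mask"))
  check_same_grid(vol, mask)
  sp <- vol$spacing
  r <- radius_mm
  reach <- floor(r / sp)
  offs <- expand.grid(dx = -reach[1]:reach[1], dy = -reach[2]:reach[2],
                      dz = -reach[3]:reach[3])
  d <- sqrt((offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 + (offs$dz * sp[3])^2)
  offs <- offs[d <= r, , drop = FALSE]
  vsum <- array(0, dim = dim(vol$values))
  vcnt <- array(0L, dim = dim(vol$values))
  for (i in seq_len(nrow(offs))) {
    b <- shift_array(vol$values, as.numeric(offs[i, ]))
    has <- !is.na(b)
    vsum[has] <- vsum[has] + b[has]
    vcnt <- vcnt + as.integer(has)
  }
  sphere_mean <- vsum / vcnt
  m <- mask$values
  peak_global <- max(sphere_mean[m])
  suv_in <- vol$values
  suv_in[!m] <- -Inf
  max_voxels <- which(suv_in == max(suv_in[m]))
  peak_local <- max(sphere_mean[max_voxels])
  c(peak_global = peak_global, peak_local = peak_local)
}
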