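#' Specification of a textured PET phantom
#'
#' Describes an ellipsoidal "tumor" of constant baseline uptake with an added
#' smoothed Gaussian random field (controllable spatial correlation length and
#' amplitude) plus white voxel noise. The random-field texture gives the
#' phantom a tunable degree of spatial autocorrelation, which is what the
#' statistical and texture feature families quantify.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param spacing numeric length-3, mm per voxel.
#' @param radii numeric length-3, ellipsoid semi-axes in mm.
#' @param base_suv baseline SUV inside the ellipsoid (> 0).
#' @param texture_corr_mm correlation length (Gaussian smoothing sigma, mm) of
#'   the texture field; 0 disables smoothing.
#' @param texture_amp amplitude (SUV standard deviation) of the texture field;
#'   0 disables texture.
#' @param noise_sd white-noise standard deviation (SUV).
#' @param seed integer seed; identical specs give bit-identical phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(40, 40, 40), spacing = c(2, 2, 2),
                         radii = c(16, 13, 11), base_suv = 6,
                         texture_corr_mm = 6, texture_amp = 1.2,
                         noise_sd = 0.3, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing <- as.numeric(spacing)
  radii <- as.numeric(radii)
  abort_if(length(grid_shape) != 3L || any(grid_shape < 1),
           "`grid_shape` must be 3 positive integers")
  abort_if(any(spacing <= 0), "`spacing` must be positive")
  abort_if(any(radii <= 0), "all ellipsoid radii must be > 0")
  abort_if(base_suv <= 0, "`base_suv` must be > 0")
  abort_if(texture_amp < 0 || noise_sd < 0 || texture_corr_mm < 0,
           "texture/noise parameters must be >= 0")
  extent <- grid_shape * spacing
  if (any(radii >= extent / 2)) {
    stop(sprintf(
      "ellipsoid exceeds grid: radii (%s) mm do not fit in half-extent (%s) mm",
      paste(radii, collapse = ", "), paste(extent / 2, collapse = ", ")),
      call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing = spacing, radii = radii,
                 base_suv = base_suv, texture_corr_mm = texture_corr_mm,
                 texture_amp = texture_amp, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable Gaussian smoothing of a 3D array, truncated at 3 sigma,
# edge-replicated padding; sigma is in voxels, per axis
gaussian_smooth3 <- function(a, sigma) {
  smooth_axis <- function(a, axis, s) {
    if (s <= 0) return(a)
    half <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-half, half), sd = s)
    k <- k / sum(k)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    d <- dim(ap)
    m <- matrix(ap, nrow = d[1])
    n <- nrow(m)
    pad <- rbind(m[rep(1L, half), , drop = FALSE], m,
                 m[rep(n, half), , drop = FALSE])
    sm <- apply(pad, 2, function(v) as.numeric(stats::filter(v, k, sides = 2)))
    sm <- sm[(half + 1):(half + n), , drop = FALSE]
    out <- array(sm, dim = d)
    aperm(out, order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax, sigma[ax])
  a
}

#' Generate a textured PET phantom and its tumor mask
#'
#' Builds the ellipsoidal mask from voxel-centre coordinates, adds a smoothed
#' Gaussian random field (normalized to unit variance, scaled by the spec
#' amplitude) and white noise inside the grid, and clips SUV at 0. Outside the
#' mask the volume is zero (cold background).
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([pet_volume()]) and `mask`
#'   ([roi_mask()]).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  sp <- spec$spacing
  centre <- d * sp / 2
  cx <- (axis_coords(d[1], sp[1]) - centre[1]) / spec$radii[1]
  cy <- (axis_coords(d[2], sp[2]) - centre[2]) / spec$radii[2]
  cz <- (axis_coords(d[3], sp[3]) - centre[3]) / spec$radii[3]
  m <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`) <= 1
  vals <- with_seed(spec$seed, {
    v <- array(0, dim = d)
    tex <- 0
    if (spec$texture_amp > 0) {
      field <- array(rnorm(prod(d)), dim = d)
      if (spec$texture_corr_mm > 0) {
        field <- gaussian_smooth3(field, spec$texture_corr_mm / sp)
      }
      field <- (field - mean(field)) / sd(field)
      tex <- spec$texture_amp * field
    }
    noise <- if (spec$noise_sd > 0) array(rnorm(prod(d), sd = spec$noise_sd),
                                          dim = d) else 0
    suv <- array(spec$base_suv, dim = d) + tex + noise
    v[m] <- suv[m]
    pmax(v, 0)
  })
  vals <- array(vals, dim = d)
  list(volume = pet_volume(vals, sp),
       mask = roi_mask(m, sp, provenance = "synthetic ellipsoid phantom"))
}

#' Specification of a synthetic patient cohort
#'
#' Describes the simulated study population: sample size, target prevalence of
#' pathologic complete response (pCR, Mandard regression grade 1), marker
#' positivity rates, a block-correlation structure for the radiomic feature
#' table (features within a block share a latent factor, emulating the tight
#' clusters of redundant texture features seen in real extractions), and the
#' true logistic coefficients that generate the outcome.
#'
#' Defaults mirror the study population the package models: n = 96 with
#' pCR prevalence 21/96 (about 22%), HER2 positivity about 19%, CD44
#' positivity about 63%, and seven radiomic feature blocks.
#'
#' @param n_patients number of patients (>= 2).
#' @param prev_response target probability of pCR; encoded via the intercept
#'   when `beta["(Intercept)"]` is `NA`.
#' @param marker_prev named probabilities of marker positivity.
#' @param clinical_prev named probabilities for the binary clinical strata
#'   (squamous histology, clinical T3-4a, clinical N2-3).
#' @param beta named true log-odds coefficients; names must be
#'   `"(Intercept)"`, clinical/marker columns or generated feature names. An
#'   `NA` intercept is calibrated so the marginal event rate matches
#'   `prev_response`.
#' @param n_blocks,block_sizes,rho_within,rho_between feature-block structure:
#'   number of blocks, features per block (scalar or per block), within-block
#'   and between-block Spearman correlation targets.
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 96, prev_response = 21 / 96,
                        marker_prev = c(her2 = 18 / 94, cd44 = 27 / 43),
                        clinical_prev = c(histology_squamous = 8 / 96,
                                          ct_t34a = 85 / 96,
                                          cn_n23 = 28 / 96),
                        beta = c("(Intercept)" = NA_real_),
                        n_blocks = 7, block_sizes = 6,
                        rho_within = 0.85, rho_between = 0.1,
                        seed = 1L) {
  abort_if(n_patients < 2, "`n_patients` must be >= 2")
  probs <- c(prev_response, marker_prev, clinical_prev)
  abort_if(any(probs < 0 | probs > 1), "probabilities must lie in [0, 1]")
  block_sizes <- rep_len(as.integer(block_sizes), n_blocks)
  rho_within <- rep_len(as.numeric(rho_within), n_blocks)
  abort_if(any(abs(rho_within) > 1) || abs(rho_between) > 1,
           "correlations must lie in [-1, 1]")
  structure(list(n_patients = as.integer(n_patients),
                 prev_response = prev_response, marker_prev = marker_prev,
                 clinical_prev = clinical_prev, beta = beta,
                 n_blocks = as.integer(n_blocks), block_sizes = block_sizes,
                 rho_within = rho_within, rho_between = rho_between,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Spearman -> Pearson correlation for the Gaussian copula
spearman_to_pearson <- function(rs) 2 * sin(pi * rs / 6)

#' Generate a block-correlated radiomic feature table
#'
#' Draws standard-normal feature columns through a Gaussian latent-factor
#' copula: features in block k load on a shared block factor so their pairwise
#' Spearman correlation targets `rho_within[k]`, while a global factor induces
#' `rho_between` across blocks. Target Spearman correlations are converted to
#' latent Pearson correlations via 2*sin(pi*rho/6).
#'
#' @param spec a [cohort_spec()].
#' @return data.frame (`n_patients` rows) of features named `b<k>_f<j>`, with
#'   attribute `block` (integer block id per column).
#' @export
generate_block_features <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  a <- spearman_to_pearson(spec$rho_between)
  cc <- spearman_to_pearson(spec$rho_within)
  for (k in seq_len(spec$n_blocks)) {
    if (a < 0 || cc[k] < a || cc[k] > 1) {
      stop(sprintf(
        "correlation structure is not positive semidefinite in block %d (within rho %.3f vs between rho %.3f)",
        k, spec$rho_within[k], spec$rho_between), call. = FALSE)
    }
  }
  n <- spec$n_patients
  p <- sum(spec$block_sizes)
  with_seed(child_seed(spec$seed, 1L), {
    g <- rnorm(n)
    out <- matrix(0, n, p)
    blocks <- integer(p)
    nm <- character(p)
    col <- 0L
    for (k in seq_len(spec$n_blocks)) {
      u <- rnorm(n)
      for (j in seq_len(spec$block_sizes[k])) {
        col <- col + 1L
        e <- rnorm(n)
        out[, col] <- sqrt(a) * g + sqrt(cc[k] - a) * u +
          sqrt(1 - cc[k]) * e
        blocks[col] <- k
        nm[col] <- sprintf("b%d_f%d", k, j)
      }
    }
    colnames(out) <- nm
    df <- as.data.frame(out)
    attr(df, "block") <- blocks
    df
  })
}

#' Generate a full synthetic cohort with known-truth outcomes
#'
#' Draws binary clinical strata and marker status from their prevalences,
#' a block-correlated radiomic feature table, and outcome labels from
#' Bernoulli(expit(X beta)) under the spec's true coefficients. Markers are
#' generated independently of the radiomic features by default, reflecting the
#' working assumption that imaging phenotype and biopsy markers carry
#' independent information.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `features` (data.frame of
#'   clinical covariates, markers and radiomic features), `labels` (0/1 pCR),
#'   `truth` (realized coefficient vector including the calibrated intercept),
#'   `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  feats <- generate_block_features(spec)
  covs <- with_seed(child_seed(spec$seed, 2L), {
    cl <- lapply(spec$clinical_prev, function(p) rbinom(n, 1, p))
    mk <- lapply(spec$marker_prev, function(p) rbinom(n, 1, p))
    as.data.frame(c(cl, mk))
  })
  X <- cbind(covs, feats)
  beta <- spec$beta
  slope_terms <- setdiff(names(beta), "(Intercept)")
  missing_terms <- setdiff(slope_terms, colnames(X))
  abort_if(length(missing_terms) > 0,
           "beta names not among generated covariates: ",
           paste(missing_terms, collapse = ", "))
  eta_rest <- if (length(slope_terms)) {
    as.numeric(as.matrix(X[, slope_terms, drop = FALSE]) %*%
                 beta[slope_terms])
  } else rep(0, n)
  b0 <- beta[["(Intercept)"]] %||% NA_real_
  if (is.na(b0)) {
    b0 <- uniroot(function(b) mean(expit(b + eta_rest)) - spec$prev_response,
                  c(-30, 30))$root
  }
  labels <- with_seed(child_seed(spec$seed, 3L),
                      rbinom(n, 1, expit(b0 + eta_rest)))
  truth <- c("(Intercept)" = b0, beta[slope_terms])
  structure(list(features = X, labels = labels, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, %d covariates, pCR prevalence %.3f\n",
              nrow(x$features), ncol(x$features), mean(x$labels)))
  invisible(x)
}
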