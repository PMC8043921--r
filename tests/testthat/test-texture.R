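# Texture families against independent brute-force oracles and the
# hand-derivable degenerate identities.

droi_from_grid <- function(g, spacing = c(1, 1, 1)) {
  structure(list(levels = g$levels, ng = g$ng, method = "fixed_bin_number",
                 param = g$ng, spacing = spacing, flags = character(0)),
            class = "discretized_roi")
}

test_that("co-occurrence counts match hand enumeration on a 2x2 grid", {
  lev <- array(c(1L, 1L, 2L, 2L), c(2, 2, 1))  # columns [1,2],[1,2]
  C <- glcm_matrix(lev, 2L, c(0, 1, 0))
  expect_equal(C, o_glcm_counts(lev, 2L, c(0, 1, 0)))
  # along +y both rows pair level 1 with 2: two ordered pairs, symmetrized
  expect_equal(C, matrix(c(0, 2, 2, 0), 2, 2))
})

test_that("single gray level zeroes distance features and flags the rest", {
  lev <- array(1L, c(3, 3, 3))
  d <- droi_from_grid(list(levels = lev, ng = 1L))
  f <- glcm_features(d)
  expect_equal(unname(f["inverse_variance"]), 0)
  expect_equal(unname(f["contrast"]), 0)
  expect_true(is.na(f["correlation"]))
  expect_match(attr(f, "flags"), "undefined:correlation", all = FALSE)
})

test_that("information correlation 2 vanishes under independent margins", {
  # product measure p(i,j) = p_i p_j => HXY2 == HXY
  p <- c(0.3, 0.7)
  P <- outer(p, p)
  f <- glcm_feature_values(P)
  expect_equal(unname(f["information_correlation_2"]), 0, tolerance = 1e-12)
})

test_that("run-length identities hold for forced configurations", {
  # single in-mask voxel: one run of length 1 at level 1
  lev <- array(NA_integer_, c(3, 3, 3)); lev[2, 2, 2] <- 1L
  d <- droi_from_grid(list(levels = lev, ng = 1L))
  f <- glrlm_features(d)
  expect_equal(unname(f["long_run_low_gray_level_emphasis"]), 1)
  # 1x4 row of level 2: along-row LRLGE = 4^2/2^2 = 4
  lev2 <- array(2L, c(4, 1, 1))
  R <- glrlm_matrix(lev2, 2L, c(1, 0, 0))
  expect_equal(unname(rl_feature_values(R, 4)["long_run_low_gray_level_emphasis"]),
               4^2 / 2^2)
})

test_that("GLCM/GLRLM/GLSZM/NGTDM match brute-force oracles on random grids", {
  dirs <- unique_directions3()
  n_bad <- 0
  for (seed in 1:220) {
    g <- random_level_grid(seed)
    d <- droi_from_grid(g)
    # GLCM + GLRLM per direction, all 13 directions
    for (k in seq_len(nrow(dirs))) {
      dd <- dirs[k, ]
      C <- glcm_matrix(g$levels, g$ng, dd)
      Co <- o_glcm_counts(g$levels, g$ng, dd)
      if (!isTRUE(all.equal(C, Co, tolerance = 1e-12))) n_bad <- n_bad + 1
      if (sum(C) > 0) {
        fv <- glcm_feature_values(C)
        fo <- o_glcm_features(Co)
        if (!isTRUE(all.equal(fv, fo, tolerance = 1e-8))) n_bad <- n_bad + 1
      }
      R <- glrlm_matrix(g$levels, g$ng, dd)
      Ro <- o_glrlm(g$levels, g$ng, dd)
      if (!isTRUE(all.equal(R, Ro, tolerance = 1e-12))) n_bad <- n_bad + 1
      nv <- sum(!is.na(g$levels))
      if (!isTRUE(all.equal(rl_feature_values(R, nv),
                            o_rl_features(Ro, nv), tolerance = 1e-8)))
        n_bad <- n_bad + 1
    }
    # GLSZM: compare zone matrices (padded to common width)
    f_sz <- glszm_features(d)
    So <- o_glszm(g$levels, g$ng)
    nv <- sum(!is.na(g$levels))
    fo_sz <- o_rl_features(So, nv, zone = TRUE)
    if (!isTRUE(all.equal(unclass(f_sz)[names(fo_sz)], fo_sz,
                          tolerance = 1e-8, check.attributes = FALSE)))
      n_bad <- n_bad + 1
    # NGTDM
    f_ng <- ngtdm_features(d)
    fo_ng <- o_ngtdm_features(o_ngtdm(g$levels, g$ng), g$ng)
    same <- all.equal(unclass(f_ng)[names(fo_ng)], fo_ng,
                      tolerance = 1e-8, check.attributes = FALSE)
    if (!isTRUE(same)) n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("uniform ROI trips the NGTDM coarseness guard", {
  lev <- array(1L, c(4, 4, 4))
  d <- droi_from_grid(list(levels = lev, ng = 1L))
  f <- ngtdm_features(d)
  expect_match(attr(f, "flags"), "coarseness_capped", all = FALSE)
  expect_equal(unname(f["coarseness"]), 1e12)
})

test_that("direction-aggregated texture is invariant to 90-degree rotation", {
  sp <- phantom_spec(grid_shape = c(14, 14, 14), spacing = c(2, 2, 2),
                     radii = c(11, 9, 7), base_suv = 4, texture_amp = 1,
                     noise_sd = 0.5, seed = 21)
  ph <- generate_phantom(sp)
  rot <- function(a) aperm(a[, dim(a)[2]:1, , drop = FALSE], c(2, 1, 3))
  v2 <- pet_volume(rot(ph$volume$values), ph$volume$spacing)
  m2 <- roi_mask(rot(ph$mask$values), ph$mask$spacing)
  d1 <- discretize(ph$volume, ph$mask, "fixed_bin_size", 0.5)
  d2 <- discretize(v2, m2, "fixed_bin_size", 0.5)
  expect_equal(glcm_features(d1), glcm_features(d2), tolerance = 1e-8)
  expect_equal(glrlm_features(d1), glrlm_features(d2), tolerance = 1e-8)
  expect_equal(glszm_features(d1), glszm_features(d2), tolerance = 1e-8)
  expect_equal(ngtdm_features(d1), ngtdm_features(d2), tolerance = 1e-8)
})

test_that("discretized texture is shift-invariant under fixed bin number", {
  sp <- phantom_spec(grid_shape = c(12, 12, 12), spacing = c(2, 2, 2),
                     radii = c(9, 8, 7), base_suv = 3, texture_amp = 0.8,
                     noise_sd = 0.4, seed = 31)
  ph <- generate_phantom(sp)
  shifted <- pet_volume(ph$volume$values + 5, ph$volume$spacing)
  d1 <- discretize(ph$volume, ph$mask, "fixed_bin_number", 8)
  d2 <- discretize(shifted, ph$mask, "fixed_bin_number", 8)
  expect_identical(d1$levels, d2$levels)
})
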