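test_that("untextured phantom is constant inside a correctly sized mask", {
  sp <- phantom_spec(grid_shape = c(21, 21, 21), spacing = c(2, 2, 2),
                     radii = c(10, 10, 10), base_suv = 5,
                     texture_amp = 0, noise_sd = 0, seed = 1)
  ph <- generate_phantom(sp)
  expect_true(all(ph$volume$values[ph$mask$values] == 5))
  expect_true(all(ph$volume$values[!ph$mask$values] == 0))
  # digitized ellipsoid voxel count vs analytic volume / voxel volume
  expected <- (4 / 3) * pi * 10^3 / 8
  expect_lt(abs(sum(ph$mask$values) - expected) / expected, 0.05)
})

test_that("phantom respects the seed contract and SUV floor", {
  sp1 <- phantom_spec(grid_shape = c(16, 16, 16), radii = c(10, 9, 8),
                      base_suv = 1, texture_amp = 2, noise_sd = 1, seed = 7)
  a <- generate_phantom(sp1)
  b <- generate_phantom(sp1)
  expect_identical(a$volume$values, b$volume$values)
  sp2 <- phantom_spec(grid_shape = c(16, 16, 16), radii = c(10, 9, 8),
                      base_suv = 1, texture_amp = 2, noise_sd = 1, seed = 8)
  cc <- generate_phantom(sp2)
  expect_identical(a$mask$values, cc$mask$values)
  expect_false(identical(a$volume$values[a$mask$values],
                         cc$volume$values[cc$mask$values]))
  expect_true(all(a$volume$values >= 0))
})

test_that("oversized ellipsoid is rejected with an explicit message", {
  expect_error(phantom_spec(grid_shape = c(10, 10, 10), spacing = c(1, 1, 1),
                            radii = c(20, 5, 5)),
               "ellipsoid exceeds grid")
})

test_that("block features reproduce the requested correlation structure", {
  spec <- cohort_spec(n_patients = 500, n_blocks = 7, block_sizes = 4,
                      rho_within = 0.9, rho_between = 0, seed = 42)
  f <- generate_block_features(spec)
  rho <- cor(f, method = "spearman")
  blocks <- attr(f, "block")
  same <- outer(blocks, blocks, `==`) & upper.tri(rho)
  diff <- outer(blocks, blocks, `!=`) & upper.tri(rho)
  expect_gt(min(abs(rho[same])), max(abs(rho[diff])))
  # average-linkage clustering at the 60% cut recovers the blocks exactly
  cl <- cluster_features(spearman_distance(f), 0.6)
  expect_equal(cl$n_clusters, 7)
  expect_equal(length(unique(paste(cl$assignment, blocks))), 7)
})

test_that("degenerate block specs behave as documented", {
  spec1 <- cohort_spec(n_patients = 40, n_blocks = 1, block_sizes = 5,
                       rho_within = 1, rho_between = 0, seed = 1)
  f1 <- generate_block_features(spec1)
  r1 <- apply(f1, 2, rank)
  expect_true(all(apply(r1, 1, function(v) length(unique(v)) == 1)))
  spec2 <- cohort_spec(n_patients = 1000, n_blocks = 4, block_sizes = 5,
                       rho_within = 0, rho_between = 0, seed = 2)
  f2 <- generate_block_features(spec2)
  rho2 <- cor(f2, method = "spearman")
  expect_lt(max(abs(rho2[upper.tri(rho2)])), 0.15)
  spec3 <- cohort_spec(n_blocks = 2, rho_within = 0.2, rho_between = 0.5)
  expect_error(generate_block_features(spec3),
               "not positive semidefinite in block 1")
})

test_that("cohort outcomes follow the generating logistic model", {
  # intercept calibrated to the study prevalence on n = 96
  spec <- cohort_spec(n_patients = 96, prev_response = 21 / 96, seed = 5)
  responders <- vapply(1:200, function(i) {
    sum(generate_cohort(cohort_spec(n_patients = 96, prev_response = 21 / 96,
                                    seed = i))$labels)
  }, 0)
  expect_lt(abs(mean(responders) - 21), 1)  # mean within 1 responder
  # null model: zero slopes, intercept 0 -> prevalence 1/2
  spec0 <- cohort_spec(n_patients = 4000,
                       beta = c("(Intercept)" = 0), seed = 9)
  expect_lt(abs(mean(generate_cohort(spec0)$labels) - 0.5), 0.03)
})

test_that("generating coefficients are recovered by refitting at n = 2000", {
  beta <- c("(Intercept)" = NA, her2 = -2, b1_f1 = 0.8)
  spec <- cohort_spec(n_patients = 2000, prev_response = 0.25, beta = beta,
                      seed = 11)
  ch <- generate_cohort(spec)
  fit <- fit_logistic(ch$features[, c("her2", "b1_f1")], ch$labels)
  est <- fit$coefficients
  se <- fit$se
  expect_lt(abs(est[["her2"]] - (-2)), 1.96 * se[["her2"]])
  expect_lt(abs(est[["b1_f1"]] - 0.8), 1.96 * se[["b1_f1"]])
})

test_that("fixture tables carry the published counts and margins", {
  ft <- fixture_tables()
  expect_equal(unname(rowSums(ft$her2_response_g1)), c(18, 76))
  expect_equal(sum(ft$cd44_response_g2), 43)
  expect_equal(unname(ft$response_g2), c(9L, 34L))
  expect_equal(sum(ft$her2_response_g1) + 2L, 96L)  # 2 missing excluded
})

test_that("fixture cohorts reproduce the published cross-tabulations", {
  g1 <- read_clinical(fixture_cohort(1))
  expect_equal(nrow(g1), 96)
  expect_equal(sum(g1$response == "pCR"), 21)
  expect_equal(as.integer(table(g1$her2, g1$response)["positive", "pCR"]), 1)
  expect_equal(sum(is.na(g1$her2)), 2)
  tt <- table(g1$her2, g1$ct_stage)
  expect_equal(as.integer(tt["positive", "T1-2"]), 0)
  expect_equal(as.integer(tt["negative", "T1-2"]), 11)
  g2 <- read_clinical(fixture_cohort(2))
  expect_equal(nrow(g2), 43)
  expect_equal(sum(g2$response == "pCR"), 9)
  t2 <- table(g2$cd44, g2$response)
  expect_equal(as.integer(t2["positive", "pCR"]), 8)
  expect_equal(as.integer(t2["negative", "non-pCR"]), 15)
  t3 <- table(g2$cd44, g2$ct_stage)
  expect_equal(as.integer(t3["negative", "T1-2"]), 1)
  expect_equal(as.integer(t3["positive", "T3-4a"]), 22)
  # all HER2+/CD44+ double positives are non-responders
  dp <- g2$her2 == "positive" & g2$cd44 == "positive"
  expect_equal(sum(dp, na.rm = TRUE), 6)
  expect_true(all(g2$response[which(dp)] == "non-pCR"))
})
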