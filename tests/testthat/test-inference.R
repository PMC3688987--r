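test_that("pearson_behavior matches the direct formula and cor.test", {
  set.seed(1)
  n <- 20
  b <- rnorm(n)
  X <- cbind(b, matrix(rnorm(n * 4), n, 4))
  res <- pearson_behavior(X, b)
  expect_equal(res$r[1], 1)
  for (j in 2:5) {
    ct <- cor.test(X[, j], b)
    expect_equal(res$r[j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p[j], ct$p.value, tolerance = 1e-12)
    # formula oracle: t = r * sqrt((n-2)/(1-r^2))
    r <- sum(scale(X[, j], scale = FALSE) * scale(b, scale = FALSE)) /
      sqrt(sum(scale(X[, j], scale = FALSE)^2) * sum(scale(b, scale = FALSE)^2))
    expect_equal(res$p[j], 2 * pt(-abs(r * sqrt((n - 2) / (1 - r^2))), n - 2),
                 tolerance = 1e-12)
  }
  expect_warning(resc <- pearson_behavior(cbind(X, 1), b), "constant")
  expect_true(is.na(resc$r[6]))
  expect_error(pearson_behavior(X[1:3, ], b[1:3]), "4 subjects")
  expect_error(pearson_behavior(X, rep(1, n)), "constant")
})

test_that("null features give correlations centred on zero", {
  set.seed(2)
  n <- 20
  b <- sample(rnorm(n))
  X <- matrix(rnorm(n * 1000), n, 1000)
  res <- pearson_behavior(X, b)
  expect_lt(abs(mean(res$r)), 0.02)
})

test_that("BH-FDR reproduces the step-up rule and an exhaustive oracle", {
  out <- fdr_bh(c(0.01, 0.02, 0.04, 0.2), q = 0.05)
  expect_equal(out$reject, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$threshold, 0.02)
  expect_equal(fdr_bh(rep(0.9, 8), 0.05)$reject, rep(FALSE, 8))
  expect_equal(fdr_bh(rep(0.9, 8), 0.05)$threshold, 0)
  set.seed(3)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    q <- runif(1, 0.01, 0.3)
    expect_identical(fdr_bh(p, q)$reject, bh_oracle(p, q))
  }
  expect_error(fdr_bh(numeric(0), 0.05), "empty")
  expect_error(fdr_bh(c(0.1, 0), 0.05), "0, 1")
})

test_that("voxelwise statistic maps match a per-voxel loop oracle", {
  set.seed(4)
  n <- 12; v <- 60
  maps <- matrix(rnorm(n * v), n, v)
  b <- rnorm(n)
  maps[, 7] <- 2 * b          # proportional voxel
  maps[, 9] <- 3              # constant voxel
  tmap <- voxelwise_stat_map(maps, b, sign = "+")
  oracle <- vapply(seq_len(v), function(j) {
    if (sd(maps[, j]) == 0) return(0)
    r <- cor(maps[, j], b)
    r * sqrt((n - 2) / (1 - r^2))
  }, numeric(1))
  # voxel 7 has |r| = 1 exactly: both implementation and oracle blow up, so
  # compare it by rank only
  expect_equal(as.numeric(tmap)[-7], oracle[-7], tolerance = 1e-10)
  expect_equal(which.max(abs(tmap)), 7L)
  expect_gt(tmap[7], 1e5)
  expect_equal(tmap[9], 0)
  tneg <- voxelwise_stat_map(maps, b, sign = "-")
  expect_equal(as.numeric(tneg), -as.numeric(tmap), tolerance = 1e-12)
})

test_that("TFCE matches the hand-worked 1D example and brute force", {
  grid1 <- voxel_grid(c(4, 1, 1))
  enh <- tfce(c(0, 2, 2, 0), grid1, E = 0.5, H = 2, dh = 1)
  # thresholds h = 1, 2; cluster extent 2 at both: sqrt(2)*1 + sqrt(2)*4
  expect_equal(enh, c(0, 5 * sqrt(2), 5 * sqrt(2), 0), tolerance = 1e-12)
  expect_equal(enh[2], 7.0711, tolerance = 1e-4)
  expect_equal(tfce(rep(0, 4), grid1), rep(0, 4))
  expect_error(tfce(c(0, 1, 1, 0), grid1, dh = -1), "dh")
})

test_that("TFCE agrees with brute-force threshold integration on random 3D maps", {
  dims <- c(9, 8, 5)
  grid <- voxel_grid(dims)
  nbrs <- neighbours_26(dims)
  set.seed(5)
  for (rep in 1:3) {
    stat <- rnorm(prod(dims), sd = 1) + 0.5
    dh <- max(stat) / 25
    expect_equal(tfce(stat, grid, E = 0.5, H = 2, dh = dh),
                 tfce_brute(stat, dims, E = 0.5, H = 2, dh = dh, nbrs = nbrs),
                 tolerance = 1e-9)
  }
})

test_that("TFCE is monotone: pointwise-dominating maps dominate after enhancement", {
  dims <- c(6, 6, 3)
  grid <- voxel_grid(dims)
  set.seed(6)
  for (rep in 1:5) {
    b <- pmax(rnorm(prod(dims)), 0)
    a <- b + runif(prod(dims), 0, 0.5)
    dh <- max(a) / 40
    ea <- tfce(a, grid, dh = dh)
    eb <- tfce(b, grid, dh = dh)
    expect_true(all(ea >= eb - 1e-12))
  }
})

test_that("small-sample permutation inference enumerates all n! permutations", {
  grid <- voxel_grid(c(4, 4, 2))
  set.seed(7)
  maps <- matrix(rnorm(5 * grid$n_voxels), 5)
  b <- rnorm(5)
  expect_warning(res <- permutation_fwe(maps, b, grid, n_perm = 500, seed = 1,
                                        two_sided = FALSE, sign = "+"),
                 "enumerating")
  expect_equal(res$n_perm, 120)
  # p-values are exact multiples of 1/120
  expect_equal(res$fwe_p_map * 120, round(res$fwe_p_map * 120), tolerance = 1e-9)
  expect_true(all(res$fwe_p_map >= 1 / 120))
  # declared invariants of the result object
  expect_equal(res$sig_mask, res$fwe_p_map < res$alpha)
  expect_equal(res$n_sig, sum(res$sig_mask))
  expect_true(all(res$tfce_map >= 0))
})

test_that("a strongly planted voxel effect is detected on its effect mask", {
  tr <- tiny_truth(n_subjects = 20, seed = 14, noise_sd = 0.2,
                   amplitude_noise_sd = 0.1,
                   amplitude_slopes = rep(0, 3),
                   spatial_slopes = c(-0.6, 0, 0))
  st <- simulate_study(tr, n_timepoints = 60)
  decs <- lapply(st$datasets, dual_regression, group_maps = tr$group_maps)
  res <- spatial_map_inference(decs, component = 1, st$behavior$score,
                               tr$grid, n_perm = 500, seed = 3,
                               two_sided = TRUE)
  planted <- tr$effect_masks[[1]]
  expect_gte(sum(res$sig_mask[planted]) / length(planted), 0.8)
  # the planted correlation is negative at those voxels
  expect_true(all(res$r_map[planted][res$sig_mask[planted]] < 0))
})

test_that("overlap statistics reproduce the published bookkeeping", {
  sig_z <- c(rep(TRUE, 173), rep(FALSE, 5000 - 173))
  sig_nonz <- c(rep(TRUE, 4782), rep(FALSE, 5000 - 4782))
  out <- overlap_stats(sig_z, sig_nonz)
  expect_equal(out$n_z, 173)
  expect_equal(out$n_nonz, 4782)
  expect_equal(out$n_overlap, 173)
  expect_equal(out$p_overlap, 100)
  disj <- overlap_stats(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE))
  expect_equal(disj$n_overlap, 0)
  expect_equal(disj$p_overlap, 0)
  expect_true(is.na(overlap_stats(rep(FALSE, 3), c(TRUE, TRUE, FALSE))$p_overlap))
  expect_error(overlap_stats(rep(TRUE, 3), rep(TRUE, 4)), "length")
})

test_that("the across-network Bonferroni thresholds match the published ones", {
  out16 <- bonferroni_across_rsns(rep(0.01, 16), alpha = 0.05)
  expect_equal(out16$threshold[1], 0.003125)
  out34 <- bonferroni_across_rsns(c(0.0008, rep(0.01, 33)), alpha = 0.05)
  expect_equal(out34$threshold[1], 0.05 / 34, tolerance = 1e-12)
  expect_equal(round(out34$threshold[1], 4), 0.0015)
  expect_true(out34$survives[1])     # 0.0008 < 0.0015
  expect_false(any(out34$survives[-1]))
})

test_that("artifact components are estimated with but excluded from inference", {
  set.seed(8)
  n <- 16; d <- 4
  b <- rnorm(n)
  netmats <- lapply(1:n, function(s)
    netmat_corr(matrix(rnorm(40 * d), 40, d)))
  labels <- c("signal", "artifact", "signal", "signal")
  res <- netmat_behavior(netmats, b, labels = labels)
  expect_equal(nrow(res), 3)               # pairs among the 3 signal comps
  expect_false(any(res$comp_1 == 2 | res$comp_2 == 2))
  amps <- matrix(rnorm(n * d), n, d)
  ares <- amplitude_behavior(amps, b, labels = labels)
  expect_equal(ares$component, c(1, 3, 4))
})

test_that("tidy and glance summarise spatial inference results", {
  grid <- voxel_grid(c(4, 4, 2))
  set.seed(9)
  maps <- matrix(rnorm(8 * grid$n_voxels), 8)
  res <- permutation_fwe(maps, rnorm(8), grid, n_perm = 100, seed = 2)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), grid$n_voxels)
  expect_named(td, c("voxel", "r", "stat", "tfce", "fwe_p", "significant"))
  gl <- glance(res)
  expect_equal(gl$n_sig, res$n_sig)
  expect_equal(gl$n_perm, 100)
})
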