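test_that("SSRT is the Go RT minus SSD, with finite-input validation", {
  expect_equal(compute_ssrt(450, 200), 250)
  expect_equal(compute_ssrt(300, 300), 0)
  expect_equal(compute_ssrt(412.7, 183.4), 229.3)
  expect_equal(compute_ssrt(c(450, 300), c(200, 300)), c(250, 0))
  expect_error(compute_ssrt(NA, 200), "finite")
  expect_error(compute_ssrt(Inf, 200), "finite")
})

test_that("group maps are compact, low-overlap, deterministic blobs", {
  gm <- make_group_maps(c(16, 16, 8), d_true = 5, blob_fwhm = 3, seed = 1)
  expect_equal(ncol(gm$maps), 5)
  expect_true(all(gm$maps >= 0))
  for (i in 1:5) {
    expect_gt(sum(gm$maps[, i] > 0.5 * max(gm$maps[, i])), 0)
    expect_gt(length(gm$effect_masks[[i]]), 0)
    expect_true(all(gm$maps[gm$effect_masks[[i]], i] > 0))
  }
  nrm <- sweep(gm$maps, 2L, sqrt(colSums(gm$maps^2)), "/")
  ov <- crossprod(nrm)
  expect_true(all(ov[upper.tri(ov)] < 0.3))
  gm2 <- make_group_maps(c(16, 16, 8), d_true = 5, blob_fwhm = 3, seed = 1)
  expect_identical(gm$maps, gm2$maps)
  gm3 <- make_group_maps(c(16, 16, 8), d_true = 5, blob_fwhm = 3, seed = 2)
  expect_false(identical(gm$maps, gm3$maps))
  expect_error(make_group_maps(c(4, 4, 1), d_true = 50, blob_fwhm = 3, seed = 1),
               "too small")
})

test_that("noiseless zero-gamma subjects are an exact linear mixture", {
  tr <- tiny_truth(noise_sd = 0, spatial_slopes = rep(0, 3), seed = 4)
  sub <- simulate_subject(tr, 2, n_timepoints = 40)
  expect_equal(sub$dataset$data, sub$timeseries %*% t(tr$group_maps),
               tolerance = 1e-12)
  # column sds hit the realized amplitudes exactly (rescaling by construction)
  expect_equal(apply(sub$timeseries, 2, sd), sub$true_amplitudes,
               tolerance = 1e-12)
})

test_that("generated timecourses match the target covariance at large t", {
  P <- matrix(c(1, -0.4, 0, -0.4, 1.2, 0.3, 0, 0.3, 0.9), 3, 3)
  tr <- tiny_truth(n_subjects = 4, precision = P, noise_sd = 0,
                   amplitude_noise_sd = 0, amplitude_slopes = rep(0, 3),
                   spatial_slopes = rep(0, 3), seed = 5)
  sub <- simulate_subject(tr, 1, n_timepoints = 50000)
  Sigma <- solve(P)
  D <- diag(sub$true_amplitudes / sqrt(diag(Sigma)))
  target <- D %*% Sigma %*% D
  emp <- cov(sub$timeseries)
  expect_equal(emp, target, tolerance = 0.02)
})

test_that("the generator is a pure, reproducible function of its seeds", {
  tr <- tiny_truth(seed = 7)
  set.seed(999)
  before <- .Random.seed
  s1 <- simulate_subject(tr, 3, n_timepoints = 20)
  expect_identical(.Random.seed, before)    # global RNG untouched
  s2 <- simulate_subject(tr, 3, n_timepoints = 20)
  expect_identical(s1$dataset$data, s2$dataset$data)
  s3 <- simulate_subject(tr, 4, n_timepoints = 20)
  expect_false(identical(s1$dataset$data, s3$dataset$data))
  tr2 <- tiny_truth(seed = 7)
  expect_identical(tr$group_maps, tr2$group_maps)
  expect_identical(tr$behavior, tr2$behavior)
})

test_that("planted amplitude couplings surface with the planted sign", {
  tr <- simulation_truth(n_subjects = 150, grid_dims = c(8, 8, 4), d_true = 3,
                         blob_fwhm = 2, amplitude_slopes = c(-0.15, -0.15, 0),
                         spatial_slopes = rep(0, 3), seed = 11)
  st <- simulate_study(tr, n_timepoints = 10)
  r <- cor(st$true_amplitudes, tr$behavior_z)
  expect_lt(r[1], -0.3)
  expect_lt(r[2], -0.3)
  expect_lt(abs(r[3]), 0.25)
  # correlation is invariant to the SSRT-scale affine map of the score
  expect_equal(cor(st$true_amplitudes, st$behavior$score), r, tolerance = 1e-10)
})

test_that("amplitude p-values are uniform under the global null", {
  # all couplings zero, identity precision: downstream amplitude-behaviour
  # p-values must be U(0,1) across replicates
  n_rep <- 500
  pvals <- vapply(seq_len(n_rep), function(rep) {
    tr <- simulation_truth(n_subjects = 12, grid_dims = c(6, 6, 3), d_true = 2,
                           blob_fwhm = 2, amplitude_slopes = c(0, 0),
                           spatial_slopes = c(0, 0), precision = diag(2),
                           noise_sd = 0.5, seed = 20000 + rep)
    st <- simulate_study(tr, n_timepoints = 12)
    amps <- do.call(rbind, lapply(st$datasets, function(ds)
      amplitude(stage1_timeseries(ds, tr$group_maps))))
    pearson_behavior(amps, st$behavior$score)$p[1]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("non-positive realized amplitudes abort with the component named", {
  tr <- tiny_truth(base_amplitudes = c(0.2, 1, 1),
                   amplitude_slopes = c(0, 0, 0),
                   amplitude_noise_sd = 2, seed = 2)
  expect_error(simulate_subject(tr, 1, n_timepoints = 20),
               "non-positive realized amplitude for component")
})

test_that("a written study round-trips through NIfTI and TSV", {
  tr <- tiny_truth(n_subjects = 3, seed = 9)
  st <- simulate_study(tr, n_timepoints = 15)
  dir <- tempfile()
  write_simulation(st, dir)
  expect_true(file.exists(file.path(dir, "behavior.tsv")))
  expect_true(file.exists(file.path(dir, "truth.json")))
  beh <- read.delim(file.path(dir, "behavior.tsv"))
  expect_equal(beh$score, st$behavior$score, tolerance = 1e-12)
  ds <- read_masked_dataset(file.path(dir, "sub-02.nii.gz"),
                            mask_file = file.path(dir, "mask.nii.gz"))
  expect_equal(ds$data, st$datasets[[2]]$data, tolerance = 1e-5)
})
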