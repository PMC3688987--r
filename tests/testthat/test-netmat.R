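# draws t x d timeseries with population precision P
draw_from_precision <- function(t, P, seed) {
  set.seed(seed)
  L <- chol(solve(P))
  matrix(rnorm(t * ncol(P)), t) %*% L
}

test_that("amplitude is the column-wise sample standard deviation", {
  x <- cbind(rep(2, 4), c(1, -1, 1, -1))
  a <- amplitude(x)
  expect_equal(a[1], 0)
  expect_equal(a[2], sqrt(4 / 3), tolerance = 1e-10)
  expect_equal(a[2], 1.1547, tolerance = 1e-4)
  expect_equal(amplitude(3 * x), 3 * a, tolerance = 1e-12)
  expect_error(amplitude(matrix(1, 1, 2)), "2 timepoints")
})

test_that("CORR matches a brute-force pairwise Pearson loop", {
  set.seed(1)
  x <- matrix(rnorm(50 * 6), 50, 6)
  nm <- netmat_corr(x)
  expect_equal(nm$values, cor_loop(x), tolerance = 1e-12)
  expect_equal(diag(nm$values), rep(1, 6))
  expect_identical(nm$method, "CORR")
  # identical / negated columns
  y <- cbind(x[, 1], x[, 1], -x[, 1] + 0 * x[, 2])
  nm2 <- netmat_corr(y)
  expect_equal(nm2$values[1, 2], 1)
  expect_equal(nm2$values[1, 3], -1)
  expect_error(netmat_corr(cbind(x[, 1], 0)), "zero")
})

test_that("unpenalised ICOV equals the closed-form partial correlation", {
  set.seed(2)
  x <- matrix(rnorm(200 * 5), 200, 5) %*% matrix(rnorm(25), 5)
  nm <- netmat_icov(x, lambda = 0)
  R <- cor(x)
  Th <- solve(R)
  expected <- -Th / sqrt(tcrossprod(diag(Th)))
  diag(expected) <- 0
  expect_equal(nm$values, expected, tolerance = 1e-6)
  expect_equal(nm$values, t(nm$values), tolerance = 1e-12)
})

test_that("partial correlation removes chain-mediated dependence", {
  # X -> Y -> Z: X and Z conditionally independent given Y
  set.seed(3)
  t <- 10000
  X <- rnorm(t); Y <- 0.8 * X + rnorm(t); Z <- 0.8 * Y + rnorm(t)
  ts <- cbind(X, Y, Z)
  full_r <- cor(X, Z)
  nm <- netmat_icov(ts, lambda = 0)
  expect_gt(full_r, 0.3)                       # marginally dependent
  expect_lt(abs(nm$values[1, 3]), 0.05)        # conditionally independent
  # regression-residual oracle agrees
  expect_equal(nm$values[1, 3], pcor_residual(ts, 1, 3), tolerance = 1e-6)
  expect_equal(nm$values[1, 2], pcor_residual(ts, 1, 2), tolerance = 1e-6)
})

test_that("stronger penalties give sparser, smaller partial correlations", {
  tr <- tiny_truth(seed = 13)
  sub <- simulate_subject(tr, 1, n_timepoints = 230)
  ts <- stage1_timeseries(sub$dataset, tr$group_maps)
  off <- function(nm) abs(nm$values[upper.tri(nm$values)])
  m10 <- mean(off(netmat_icov(ts, lambda = 10)))
  m200 <- mean(off(netmat_icov(ts, lambda = 200)))
  expect_lte(m200, m10)
})

test_that("ICOV recovers the support of a planted sparse precision", {
  # chain precision: true edges (1,2),(2,3),(3,4),(4,5)
  P <- diag(5)
  for (i in 1:4) { P[i, i + 1] <- -0.35; P[i + 1, i] <- -0.35 }
  f1s <- vapply(1:5, function(s) {
    ts <- draw_from_precision(230, P, seed = 100 + s)
    nm <- netmat_icov(ts, lambda = 50)
    est <- abs(nm$values[upper.tri(nm$values)]) > 1e-8
    truth <- P[upper.tri(P)] != 0
    tp <- sum(est & truth)
    2 * tp / (2 * tp + sum(est & !truth) + sum(!est & truth))
  }, numeric(1))
  expect_gt(mean(f1s), 0.8)
})

test_that("gICOV interpolates between per-subject and pooled solutions", {
  set.seed(4)
  covs <- lapply(1:6, function(s) {
    x <- matrix(rnorm(60 * 4), 60, 4)
    cor(x %*% diag(runif(4, 0.5, 2)) + 0.3 * x[, c(2, 3, 4, 1)])
  })
  g0 <- netmat_gicov(covs, lambda = 10, tau = 0)
  icov_ref <- lapply(covs, icov_from_cov, lambda = 10)
  for (s in 1:6) expect_equal(g0[[s]]$values, icov_ref[[s]]$values,
                              tolerance = 1e-8)
  g1 <- netmat_gicov(covs, lambda = 10, tau = 1)
  for (s in 2:6) expect_equal(g1[[s]]$values, g1[[1]]$values, tolerance = 1e-12)
  # across-subject edge variance non-increasing in tau
  edge_var <- function(g) {
    E <- sapply(g, function(nm) nm$values[upper.tri(nm$values)])
    mean(apply(E, 1, var))
  }
  vars <- vapply(c(0, 0.25, 0.5, 1), function(tau)
    edge_var(netmat_gicov(covs, lambda = 10, tau = tau)), numeric(1))
  expect_true(all(diff(vars) <= 1e-12))
  expect_error(netmat_gicov(covs, tau = 1.5), "tau")
})

test_that("the Fisher transform is atanh off-diagonal with a zero diagonal", {
  V <- matrix(c(1, 0.5, -0.3, 0.5, 1, 0, -0.3, 0, 1), 3, 3)
  nm <- netmat_corr(matrix(rnorm(30), 10, 3))
  nm$values <- V
  fz <- fisher_z(nm)
  expect_equal(fz$values[1, 2], 0.5 * log(3), tolerance = 1e-12)
  expect_equal(fz$values[1, 2], 0.5493, tolerance = 1e-4)
  expect_equal(fz$values[1, 3], -atanh(0.3))
  expect_equal(fz$values[2, 3], 0)
  expect_equal(diag(fz$values), rep(0, 3))
  expect_true(fz$fisher)
  # antisymmetry
  nm_neg <- nm; nm_neg$values <- -V; diag(nm_neg$values) <- 1
  expect_equal(fisher_z(nm_neg)$values, -fz$values)
  expect_error(fisher_z(fz), "already")
  nm_bad <- nm; nm_bad$values[1, 2] <- nm_bad$values[2, 1] <- 1
  expect_error(fisher_z(nm_bad), "degenerate")
})

test_that("full correlations dominate partial correlations on chain data", {
  P <- diag(5)
  for (i in 1:4) { P[i, i + 1] <- -0.35; P[i + 1, i] <- -0.35 }
  ts <- draw_from_precision(230, P, seed = 7)
  off <- function(V) mean(abs(V[upper.tri(V)]))
  expect_gte(off(netmat_corr(ts)$values),
             off(netmat_icov(ts, lambda = 10)$values))
})
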