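#' Pearson correlation of features with behaviour across subjects
#'
#' One correlation per feature column, with two-sided p-values from the t
#' distribution on `n - 2` degrees of freedom. Constant feature columns get
#' `NA` (flagged with a warning) and are meant to be excluded from multiple-
#' comparison correction.
#'
#' @param features subjects x k numeric matrix.
#' @param behavior numeric vector of per-subject scores (non-constant, n >= 4).
#' @return tibble with columns `feature`, `r`, `p`.
#' @export
pearson_behavior <- function(features, behavior) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  if (length(behavior) != n) stop("behavior length must match subjects", call. = FALSE)
  if (stats::sd(behavior) == 0) stop("behavior is constant", call. = FALSE)
  b <- behavior - mean(behavior)
  Xc <- sweep(X, 2L, colMeans(X))
  cn <- unname(sqrt(colSums(Xc^2)))
  const <- cn == 0
  r <- as.numeric(crossprod(Xc, b)) / (cn * sqrt(sum(b^2)))
  r[const] <- NA_real_
  r <- pmin(pmax(r, -1), 1)
  tval <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tval), df = n - 2)
  p[const] <- NA_real_
  if (any(const))
    warning(sprintf("%d constant feature column(s): r undefined, excluded from correction",
                    sum(const)))
  nm <- colnames(X)
  tibble::tibble(feature = if (is.null(nm)) seq_len(ncol(X)) else nm,
                 r = r, p = p)
}

#' Benjamini-Hochberg step-up false-discovery-rate control
#'
#' Two-sided p-values enter the standard BH step-up procedure; testing both
#' correlation signs through two-sided p-values realises the extra factor-of-
#' two correction for signed tests.
#'
#' @param p_values p-values in (0, 1]; `NA`s are not allowed here (exclude
#'   degenerate features beforehand).
#' @param q target FDR level in (0, 1).
#' @return list with `reject` (logical), `threshold` (largest rejected p, 0 if
#'   none) and `q`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  p <- as.numeric(p_values)
  if (length(p) == 0) stop("empty p-value list", call. = FALSE)
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  if (q <= 0 || q >= 1) stop("`q` must be in (0, 1)", call. = FALSE)
  reject <- stats::p.adjust(p, method = "BH") <= q
  list(reject = reject,
       threshold = if (any(reject)) max(p[reject]) else 0,
       q = q)
}

#' Amplitude-versus-behaviour analysis
#'
#' Correlates each (signal) network's amplitude with the behavioural score and
#' applies BH-FDR across the tested networks.
#'
#' @param amplitudes subjects x d matrix of network amplitudes.
#' @param behavior per-subject scores.
#' @param labels optional per-component `"signal"`/`"artifact"` labels;
#'   artifact components are excluded from testing.
#' @param q FDR level.
#' @return tibble: `component`, `r`, `p`, `significant_fdr`, `q_level`.
#' @export
amplitude_behavior <- function(amplitudes, behavior, labels = NULL, q = 0.05) {
  A <- as.matrix(amplitudes)
  keep <- seq_len(ncol(A))
  if (!is.null(labels)) {
    stopifnot(length(labels) == ncol(A))
    keep <- which(labels == "signal")
  }
  res <- pearson_behavior(A[, keep, drop = FALSE], behavior)
  ok <- !is.na(res$p)
  sig <- logical(nrow(res))
  if (any(ok)) sig[ok] <- fdr_bh(res$p[ok], q)$reject
  tibble::tibble(component = keep, r = res$r, p = res$p,
                 significant_fdr = sig, q_level = q)
}

#' Netmat-edge-versus-behaviour analysis
#'
#' Fisher-transforms each subject's network matrix, takes every unordered pair
#' of signal components (matrix elements involving artifact components are
#' discarded here, after estimation), correlates each edge with behaviour
#' across subjects and applies BH-FDR across edges.
#'
#' @param netmats list of `netmat` objects, one per subject (same method).
#' @param behavior per-subject scores.
#' @param labels optional per-component labels; artifact components' edges are
#'   dropped.
#' @param q FDR level.
#' @param fisher apply [fisher_z()] first (skipped for matrices already
#'   transformed)?
#' @return tibble: `comp_1`, `comp_2`, `r`, `p`, `significant_fdr`, `q_level`,
#'   `method`.
#' @export
netmat_behavior <- function(netmats, behavior, labels = NULL, q = 0.05,
                            fisher = TRUE) {
  stopifnot(is.list(netmats), length(netmats) >= 4,
            all(vapply(netmats, inherits, logical(1), "netmat")))
  d <- ncol(netmats[[1]]$values)
  keep <- seq_len(d)
  if (!is.null(labels)) {
    stopifnot(length(labels) == d)
    keep <- which(labels == "signal")
  }
  pairs <- which(upper.tri(diag(length(keep))), arr.ind = TRUE)
  feats <- t(vapply(netmats, function(nm) {
    V <- nm$values
    if (fisher && !nm$fisher) V <- fisher_z(nm)$values
    V[keep, keep, drop = FALSE][upper.tri(V[keep, keep, drop = FALSE])]
  }, numeric(nrow(pairs))))
  res <- pearson_behavior(feats, behavior)
  ok <- !is.na(res$p)
  sig <- logical(nrow(res))
  if (any(ok)) sig[ok] <- fdr_bh(res$p[ok], q)$reject
  tibble::tibble(comp_1 = keep[pairs[, 1]], comp_2 = keep[pairs[, 2]],
                 r = res$r, p = res$p, significant_fdr = sig, q_level = q,
                 method = netmats[[1]]$method)
}

#' Voxelwise correlation statistic map
#'
#' Per-voxel Pearson correlation of subject map values with behaviour,
#' converted to the t statistic on `n - 2` degrees of freedom. Zero-variance
#' voxels get statistic 0.
#'
#' @param subject_maps subjects x voxels matrix.
#' @param behavior per-subject scores (>= 4 subjects).
#' @param sign `"+"` tests positive correlations; `"-"` negates the map so
#'   negative correlations become positive statistics.
#' @return numeric vector of t statistics (one per voxel), with the r values
#'   as attribute `"r"`.
#' @export
voxelwise_stat_map <- function(subject_maps, behavior, sign = c("+", "-")) {
  sign <- match.arg(sign)
  X <- as.matrix(subject_maps)
  n <- nrow(X)
  if (n < 4) stop("need at least 4 subjects", call. = FALSE)
  b <- behavior - mean(behavior)
  Xc <- sweep(X, 2L, colMeans(X))
  cn <- sqrt(colSums(Xc^2))
  denom <- cn * sqrt(sum(b^2))
  r <- as.numeric(crossprod(Xc, b))
  r <- ifelse(denom > 0, r / denom, 0)
  r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  tval[cn == 0] <- 0
  if (sign == "-") tval <- -tval
  attr(tval, "r") <- ifelse(cn == 0, 0, r)
  tval
}

#' Threshold-free cluster enhancement
#'
#' `TFCE(p) = sum over h = dh, 2dh, ... <= max(stat) of e(h)^E * h^H * dh`,
#' where `e(h)` is the voxel count of the 26-connected suprathreshold cluster
#' containing `p` at height `h`. Negative statistic values are treated as 0
#' (enhance one sign at a time).
#'
#' @param stat_map numeric vector of in-mask statistics, or a 3D array.
#' @param grid a [voxel_grid()].
#' @param E extent exponent (default 0.5).
#' @param H height exponent (default 2).
#' @param dh threshold step; `NULL` uses `max(stat) / 100`.
#' @return Enhanced map, same shape as the input.
#' @export
tfce <- function(stat_map, grid, E = 0.5, H = 2, dh = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (!is.null(dh) && dh <= 0) stop("`dh` must be positive", call. = FALSE)
  is_vec <- is.null(dim(stat_map))
  vol <- if (is_vec) unmask_volumes(stat_map, grid) else stat_map
  out <- tfce_cpp(as.numeric(vol), grid$dims, E = E, H = H,
                  dh = if (is.null(dh)) 0 else dh, nsteps_default = 100L)
  if (is_vec) {
    as.numeric(out)[which(grid$mask)]
  } else {
    array(out, dim = grid$dims)
  }
}

# all n! permutations of 1..n (small n only)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation family-wise-error inference on spatial maps
#'
#' Permutes the behaviour vector across subjects, recomputes the TFCE-enhanced
#' correlation statistic map for each permutation, and records the maximum
#' enhanced statistic; the per-voxel FWE-corrected p is the proportion of
#' permutation maxima (identity permutation always included) at or above the
#' observed enhanced value. Two-sided inference tests each sign against its
#' own max-statistic null and doubles the smaller p (capped at 1).
#'
#' @param subject_maps subjects x in-mask-voxels matrix.
#' @param behavior per-subject scores (>= 5 subjects).
#' @param grid a [voxel_grid()].
#' @param n_perm number of permutations (>= 100); if `n_perm >= n!` the exact
#'   enumeration of all `n!` permutations is used instead, with a warning.
#' @param alpha significance level for the returned mask.
#' @param seed RNG seed for the permutation engine (required for
#'   reproducibility).
#' @param two_sided test both signs (doubled p) or only `sign`.
#' @param sign when `two_sided = FALSE`, which sign to test.
#' @param E,H,nsteps TFCE parameters; the threshold step is the permutation
#'   map's maximum divided by `nsteps`.
#' @return An object of class `spatial_inference`: `r_map`, `stat_map`,
#'   `tfce_map` (per-voxel enhanced statistic of the tested sign(s)),
#'   `fwe_p_map`, `sig_mask`, `n_sig`, `min_p`, plus the permutation maxima
#'   and settings.
#' @export
permutation_fwe <- function(subject_maps, behavior, grid, n_perm = 500,
                            alpha = 0.05, seed, two_sided = TRUE,
                            sign = c("-", "+"), E = 0.5, H = 2, nsteps = 100) {
  sign <- match.arg(sign)
  X <- as.matrix(subject_maps)
  n <- nrow(X)
  if (n < 5) stop("need at least 5 subjects", call. = FALSE)
  if (n_perm < 100) stop("`n_perm` must be >= 100", call. = FALSE)
  if (missing(seed)) stop("`seed` is required for the permutation engine", call. = FALSE)
  stopifnot(inherits(grid, "voxel_grid"), ncol(X) == grid$n_voxels)

  nfact <- factorial(n)
  if (!is.finite(nfact) || n_perm < nfact) {
    perms <- with_local_seed(seed, {
      cbind(seq_len(n),
            vapply(seq_len(n_perm - 1L), function(i) sample.int(n),
                   integer(n)))
    })
  } else {
    warning(sprintf("n_perm >= n! = %d: enumerating all permutations exactly", nfact))
    perms <- t(all_permutations(n))
    n_perm <- ncol(perms)
  }
  bperm <- matrix(behavior[perms], nrow = n)

  Xfull <- matrix(0, n, prod(grid$dims))
  Xfull[, which(grid$mask)] <- X
  maxima <- perm_max_tfce_cpp(Xfull, bperm, grid$dims, E = E, H = H,
                              nsteps = nsteps)

  tstat <- voxelwise_stat_map(X, behavior, sign = "+")
  r_map <- attr(tstat, "r")
  enh_pos <- tfce(pmax(as.numeric(tstat), 0), grid, E = E, H = H)
  enh_neg <- tfce(pmax(-as.numeric(tstat), 0), grid, E = E, H = H)

  # the identity permutation is included, so p >= 1/n_perm; compare with a
  # relative epsilon because the observed map and the permutation maxima are
  # computed by different (equally valid) summation orders
  p_from_max <- function(obs, mx)
    vapply(obs, function(o) sum(mx >= o - 1e-9 * abs(o)) / length(mx),
           numeric(1))
  p_pos <- p_from_max(enh_pos, maxima[, 1])
  p_neg <- p_from_max(enh_neg, maxima[, 2])

  if (two_sided) {
    fwe_p <- pmin(1, 2 * pmin(p_pos, p_neg))
    tfce_map <- pmax(enh_pos, enh_neg)
  } else if (sign == "+") {
    fwe_p <- p_pos
    tfce_map <- enh_pos
  } else {
    fwe_p <- p_neg
    tfce_map <- enh_neg
  }
  sig <- fwe_p < alpha
  structure(list(r_map = r_map, stat_map = as.numeric(tstat),
                 tfce_map = tfce_map, fwe_p_map = fwe_p, sig_mask = sig,
                 n_sig = sum(sig), min_p = min(fwe_p), grid = grid,
                 perm_maxima = maxima, n_perm = n_perm, alpha = alpha,
                 two_sided = two_sided, sign = sign, seed = seed),
            class = "spatial_inference")
}

#' @export
print.spatial_inference <- function(x, ...) {
  cat(sprintf("<spatial_inference> %d voxels, %d permutations%s: %d significant (alpha %.3g), min FWE p = %.4g\n",
              length(x$fwe_p_map), x$n_perm,
              if (x$two_sided) ", two-sided" else paste0(", sign ", x$sign),
              x$n_sig, x$alpha, x$min_p))
  invisible(x)
}

#' Overlap between two significance masks
#'
#' Consistency statistics between results based on z-transformed and original
#' (non-z) spatial maps: the voxel counts of each mask, their intersection,
#' and the percentage of z-mask voxels inside the non-z mask (`NA` when the
#' z mask is empty).
#'
#' @param sig_z,sig_nonz logical vectors on the same grid.
#' @return tibble: `n_z`, `n_nonz`, `n_overlap`, `p_overlap` (percent).
#' @export
overlap_stats <- function(sig_z, sig_nonz) {
  if (length(sig_z) != length(sig_nonz))
    stop("masks have different lengths", call. = FALSE)
  n_z <- sum(sig_z)
  n_overlap <- sum(sig_z & sig_nonz)
  tibble::tibble(n_z = n_z, n_nonz = sum(sig_nonz), n_overlap = n_overlap,
                 p_overlap = if (n_z == 0) NA_real_ else 100 * n_overlap / n_z)
}

#' Bonferroni correction across networks
#'
#' Flags networks whose spatially-FWE-corrected minimum p survives division of
#' `alpha` by the number of networks tested (e.g. 0.05/16 = 0.003125).
#'
#' @param min_p_per_rsn vector of per-network minimum FWE-corrected p-values.
#' @param n_rsn number of networks in the family (defaults to the vector
#'   length).
#' @param alpha family-wise level.
#' @return tibble: `rsn`, `min_p`, `survives`, `threshold`.
#' @export
bonferroni_across_rsns <- function(min_p_per_rsn, n_rsn = length(min_p_per_rsn),
                                   alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  thr <- alpha / n_rsn
  tibble::tibble(rsn = seq_along(min_p_per_rsn), min_p = min_p_per_rsn,
                 survives = min_p_per_rsn < thr, threshold = thr)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.spatial_inference <- function(x, ...) {
  tibble::tibble(voxel = seq_along(x$r_map), r = x$r_map, stat = x$stat_map,
                 tfce = x$tfce_map, fwe_p = x$fwe_p_map,
                 significant = x$sig_mask)
}

#' @export
glance.spatial_inference <- function(x, ...) {
  tibble::tibble(n_voxels = length(x$r_map), n_sig = x$n_sig, min_p = x$min_p,
                 alpha = x$alpha, n_perm = x$n_perm, two_sided = x$two_sided)
}
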