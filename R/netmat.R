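# L1-penalised Gaussian precision estimation (graphical lasso), block
# coordinate descent over columns with an inner lasso coordinate descent.
# The penalty applies to off-diagonal entries only. Returns the precision
# matrix Theta. rho = 0 converges to solve(S) for positive-definite S.
glasso_precision <- function(S, rho, tol = 1e-8, max_sweeps = 500) {
  d <- ncol(S)
  if (d == 1L) return(matrix(1 / S, 1, 1))
  W <- S
  B <- matrix(0, d - 1L, d)    # warm-started lasso coefficients per column
  off_scale <- mean(abs(S[upper.tri(S)]))
  if (off_scale == 0) off_scale <- 1
  for (sweep_i in seq_len(max_sweeps)) {
    W_old <- W
    for (j in seq_len(d)) {
      idx <- seq_len(d)[-j]
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      b <- B[, j]
      # inner coordinate descent for: min 1/2 b'W11 b - s12'b + rho |b|_1
      for (inner in seq_len(1000L)) {
        b_old <- b
        for (k in seq_len(d - 1L)) {
          r_k <- s12[k] - sum(W11[k, ] * b) + W11[k, k] * b[k]
          b[k] <- sign(r_k) * max(abs(r_k) - rho, 0) / W11[k, k]
        }
        if (max(abs(b - b_old)) < tol * off_scale) break
      }
      B[, j] <- b
      w12 <- W11 %*% b
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    if (max(abs(W - W_old)) < tol * off_scale) break
  }
  if (sweep_i == max_sweeps && max(abs(W - W_old)) >= tol * off_scale)
    stop(sprintf("graphical lasso did not converge in %d sweeps (last change %.2e)",
                 max_sweeps, max(abs(W - W_old))), call. = FALSE)
  Theta <- matrix(0, d, d)
  for (j in seq_len(d)) {
    idx <- seq_len(d)[-j]
    theta_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    Theta[j, j] <- theta_jj
    Theta[idx, j] <- -B[, j] * theta_jj
  }
  (Theta + t(Theta)) / 2
}

# precision -> partial correlation, diagonal 0, exactly symmetric
precision_to_partial <- function(Theta) {
  dsd <- sqrt(diag(Theta))
  P <- -Theta / tcrossprod(dsd)
  P <- (P + t(P)) / 2
  diag(P) <- 0
  P
}

new_netmat <- function(values, method, lambda = NA_real_, tau = NA_real_,
                       fisher = FALSE) {
  values <- (values + t(values)) / 2
  structure(list(values = values, method = method, lambda = lambda, tau = tau,
                 fisher = fisher),
            class = "netmat")
}

#' @export
print.netmat <- function(x, ...) {
  cat(sprintf("<netmat> %s, %d x %d%s%s%s\n", x$method, nrow(x$values),
              ncol(x$values),
              if (!is.na(x$lambda)) sprintf(", lambda = %g", x$lambda) else "",
              if (!is.na(x$tau)) sprintf(", tau = %g", x$tau) else "",
              if (x$fisher) ", Fisher z" else ""))
  invisible(x)
}

#' Network amplitudes from raw stage-1 timeseries
#'
#' The amplitude of a network is the sample standard deviation of its raw
#' (pre-normalization) stage-1 timeseries.
#'
#' @param timeseries_raw t x d matrix, t >= 2.
#' @return numeric(d) of nonnegative amplitudes.
#' @export
amplitude <- function(timeseries_raw) {
  x <- as.matrix(timeseries_raw)
  if (nrow(x) < 2) stop("need at least 2 timepoints", call. = FALSE)
  apply(x, 2L, stats::sd)
}

#' Full-correlation network matrix (CORR)
#'
#' @param timeseries t x d matrix; no zero-variance column allowed.
#' @return A `netmat` of pairwise Pearson correlations (diagonal 1).
#' @export
netmat_corr <- function(timeseries) {
  x <- as.matrix(timeseries)
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop(sprintf("component %s has zero-variance timeseries",
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  new_netmat(stats::cor(x), "CORR")
}

#' Regularized partial-correlation network matrix (ICOV)
#'
#' Estimates a sparse precision matrix by L1-penalised Gaussian maximum
#' likelihood on the sample correlation matrix of the timeseries (penalty
#' `rho = lambda / 1000` on off-diagonal entries), then converts it to partial
#' correlations `-Theta_ij / sqrt(Theta_ii * Theta_jj)` with zero diagonal.
#' At `lambda = 0` this is the closed-form partial correlation from the
#' inverse correlation matrix.
#'
#' @param timeseries t x d matrix (t > 2) or a `netmat`-sized covariance via
#'   [icov_from_cov()].
#' @param lambda nonnegative regularization strength (the published sweeps use
#'   5-200; 10 is the working default).
#' @return A `netmat` with `method = "ICOV"`.
#' @export
netmat_icov <- function(timeseries, lambda = 10) {
  x <- as.matrix(timeseries)
  if (nrow(x) <= 2) stop("need t > 2 timepoints", call. = FALSE)
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  x <- normalize_columns(x, "component timeseries")
  S <- crossprod(x) / (nrow(x) - 1)
  icov_from_cov(S, lambda)
}

#' ICOV from a covariance/correlation matrix
#'
#' @param S d x d symmetric positive-definite covariance (correlation scale).
#' @param lambda nonnegative regularization strength; penalty `lambda / 1000`.
#' @return A `netmat` with `method = "ICOV"`.
#' @export
icov_from_cov <- function(S, lambda = 10) {
  S <- (S + t(S)) / 2
  Theta <- glasso_precision(S, rho = lambda / 1000)
  nm <- new_netmat(precision_to_partial(Theta), "ICOV", lambda = lambda)
  nm
}

#' Group-regularized partial correlation (gICOV)
#'
#' Shrinks each subject's covariance toward the group mean covariance,
#' `S*_s = (1 - tau) * S_s + tau * mean(S)`, then applies the ICOV estimator
#' per subject. `tau = 0` reproduces per-subject ICOV; `tau = 1` returns the
#' group solution for every subject.
#'
#' @param subject_covariances list of d x d covariance matrices (correlation
#'   scale), one per subject; at least 2 subjects.
#' @param lambda nonnegative regularization strength as in [netmat_icov()].
#' @param tau group-shrinkage weight in `[0, 1]`.
#' @return list of `netmat` objects with `method = "GICOV"`.
#' @export
netmat_gicov <- function(subject_covariances, lambda = 10, tau = 0.5) {
  stopifnot(is.list(subject_covariances), length(subject_covariances) >= 2)
  if (!is.numeric(tau) || length(tau) != 1L || tau < 0 || tau > 1)
    stop("`tau` must be in [0, 1]", call. = FALSE)
  d <- ncol(subject_covariances[[1]])
  for (S in subject_covariances)
    if (!identical(dim(as.matrix(S)), c(d, d)))
      stop("all covariances must be d x d", call. = FALSE)
  Sbar <- Reduce(`+`, subject_covariances) / length(subject_covariances)
  lapply(subject_covariances, function(S) {
    nm <- icov_from_cov((1 - tau) * S + tau * Sbar, lambda)
    nm$method <- "GICOV"
    nm$tau <- tau
    nm
  })
}

#' Fisher r-to-z transform of a network matrix
#'
#' Elementwise `atanh` on the off-diagonal entries; the diagonal is set to 0.
#'
#' @param netmat a `netmat` with `fisher = FALSE` and off-diagonal magnitudes
#'   strictly below 1.
#' @return The transformed `netmat` with `fisher = TRUE`.
#' @export
fisher_z <- function(netmat) {
  stopifnot(inherits(netmat, "netmat"))
  if (netmat$fisher) stop("netmat is already Fisher-transformed", call. = FALSE)
  V <- netmat$values
  off <- V[row(V) != col(V)]
  if (any(abs(off) >= 1))
    stop("off-diagonal |value| >= 1: degenerate correlation", call. = FALSE)
  Z <- atanh(V * (row(V) != col(V)))
  diag(Z) <- 0
  out <- netmat
  out$values <- Z
  out$fisher <- TRUE
  out
}

#' Per-subject feature extraction for a study
#'
#' Runs stage-1 dual regression per subject against the group maps, collects
#' amplitudes and network matrices. Partial-correlation estimation uses all
#' components (artifacts included, so their variance is conditioned away);
#' discarding artifact rows/columns is deferred to the inference layer.
#'
#' @param datasets list of [masked_dataset()].
#' @param group_maps `component_maps` or voxels x d matrix.
#' @param lambda ICOV/gICOV regularization strength.
#' @param tau gICOV group-shrinkage weight.
#' @param methods subset of `c("CORR", "ICOV", "GICOV")`.
#' @return list with `amplitudes` (subjects x d matrix), `timeseries` (list of
#'   raw t x d matrices), and one list of `netmat`s per requested method.
#' @export
extract_features <- function(datasets, group_maps, lambda = 10, tau = 0.5,
                             methods = c("CORR", "ICOV", "GICOV")) {
  ts_list <- lapply(datasets, stage1_timeseries, group_maps = group_maps)
  out <- list(amplitudes = do.call(rbind, lapply(ts_list, amplitude)),
              timeseries = ts_list)
  if ("CORR" %in% methods) out$corr <- lapply(ts_list, netmat_corr)
  if ("ICOV" %in% methods) out$icov <- lapply(ts_list, netmat_icov, lambda = lambda)
  if ("GICOV" %in% methods) {
    covs <- lapply(ts_list, function(x) {
      xn <- normalize_columns(as.matrix(x), "component timeseries")
      crossprod(xn) / (nrow(xn) - 1)
    })
    out$gicov <- netmat_gicov(covs, lambda = lambda, tau = tau)
  }
  out
}
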