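#' Temporally concatenate subjects and reduce to d dimensions
#'
#' Each subject's data matrix is demeaned over time, subjects are stacked along
#' the time dimension, and each voxel is variance-normalized by an estimate of
#' its noise standard deviation (the residual sd after removing a first-pass
#' rank-`d` PCA fit, floored at a small fraction of the largest residual sd so
#' that noise-free voxels are left on a common scale). The normalized matrix
#' is then reduced to `d` dimensions by PCA over the concatenated time
#' dimension. The returned voxel-space matrix is whitened: its rows have
#' exactly zero mean, unit variance and zero pairwise covariance over voxels.
#'
#' @param datasets list of [masked_dataset()] sharing one grid/mask.
#' @param d target dimensionality; must not exceed the data rank.
#' @return list of class `ica_reduction`: `whitened` (d x voxels), `basis`
#'   (total-timepoints x d PCA scores for back-projection), `V` (voxels x d
#'   right singular basis of the normalized data), `dewhiten` (d x d matrix
#'   mapping whitened rows back to `t(V)`), `sdev` (singular values /
#'   sqrt(total_t - 1)), `voxel_noise_sd` (the normalization vector), `grid`,
#'   `total_variance`.
#' @export
concatenate_and_reduce <- function(datasets, d) {
  stopifnot(length(datasets) >= 1, all(vapply(datasets, inherits, logical(1),
                                              "masked_dataset")))
  grid <- datasets[[1]]$grid
  for (ds in datasets)
    if (!identical(ds$grid$mask, grid$mask) || !identical(ds$grid$dims, grid$dims))
      stop("all datasets must share one grid/mask", call. = FALSE)
  total_t <- sum(vapply(datasets, function(ds) nrow(ds$data), numeric(1)))
  if (total_t <= d)
    stop(sprintf("d = %d exceeds the concatenated time dimension (%d)", d, total_t),
         call. = FALSE)
  X <- do.call(rbind, lapply(datasets, function(ds)
    sweep(ds$data, 2L, colMeans(ds$data))))
  v <- ncol(X)

  top_right_basis <- function(X) {
    if (v <= total_t) {
      e <- eigen(crossprod(X), symmetric = TRUE)          # v x v
      if (d > sum(e$values > max(e$values) * 1e-10))
        stop(sprintf("d = %d exceeds the rank of the concatenated data", d),
             call. = FALSE)
      list(V = e$vectors[, seq_len(d), drop = FALSE],
           sv = sqrt(pmax(e$values[seq_len(d)], 0)))
    } else {
      e <- eigen(tcrossprod(X), symmetric = TRUE)         # T x T
      if (d > sum(e$values > max(e$values) * 1e-10))
        stop(sprintf("d = %d exceeds the rank of the concatenated data", d),
             call. = FALSE)
      sv <- sqrt(pmax(e$values[seq_len(d)], 0))
      list(V = crossprod(X, e$vectors[, seq_len(d), drop = FALSE]) %*%
             diag(1 / sv, d), sv = sv)
    }
  }

  # pass 1: noise-variance estimate per voxel = residual sd after removing
  # the rank-d fit
  p1 <- top_right_basis(X)
  res_ss <- pmax(colSums(X^2) - rowSums((p1$V %*% diag(p1$sv, d))^2), 0)
  noise_sd <- sqrt(res_ss / total_t)
  # floor relative to the DATA scale, so that (near-)noiseless voxels are
  # normalized by a common constant rather than by numerical residue
  floor_sd <- sqrt(max(colSums(X^2)) / total_t) * 1e-6
  if (floor_sd == 0) floor_sd <- 1
  noise_sd <- pmax(noise_sd, floor_sd)
  X <- sweep(X, 2L, noise_sd, "/")

  # pass 2: PCA of the normalized data
  p2 <- top_right_basis(X)
  V <- p2$V
  P <- t(V)                                # d x v, orthonormal rows
  # exact whitening over voxels: demean rows, decorrelate, unit variance
  Pc <- P - rowMeans(P)
  C <- tcrossprod(Pc) / (v - 1)
  ec <- eigen(C, symmetric = TRUE)
  Wh <- ec$vectors %*% diag(1 / sqrt(ec$values), d) %*% t(ec$vectors)
  whitened <- Wh %*% Pc
  dewhiten <- ec$vectors %*% diag(sqrt(ec$values), d) %*% t(ec$vectors)
  structure(list(whitened = whitened, basis = X %*% V, V = V,
                 dewhiten = dewhiten, sdev = p2$sv / sqrt(total_t - 1),
                 voxel_noise_sd = noise_sd, grid = grid,
                 total_variance = sum(X^2)),
            class = "ica_reduction")
}

# symmetric decorrelation: W <- (W W')^{-1/2} W
sym_decorrelate <- function(W) {
  e <- eigen(tcrossprod(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(e$values), nrow(W)) %*% t(e$vectors) %*% W
}

#' Fixed-point spatial ICA with symmetric decorrelation
#'
#' Estimates `d` maximally non-Gaussian spatial components from a whitened
#' voxels-space matrix using the log-cosh (tanh) contrast and parallel
#' (symmetric) fixed-point updates. Each component's sign is fixed so its
#' skewness is nonnegative, and components are ranked by the variance of the
#' concatenated data they explain.
#'
#' @param reduction an `ica_reduction` from [concatenate_and_reduce()], or a
#'   plain whitened d x voxels matrix (then explained variance is computed in
#'   whitened space).
#' @param tol convergence tolerance on the update angle.
#' @param max_iter maximum fixed-point iterations; non-convergence returns the
#'   current estimate with a warning and `converged = FALSE`.
#' @param seed RNG seed for the random orthogonal initialisation.
#' @return An object of class `component_maps`: `maps` (voxels x d, each
#'   column unit variance), `labels` (all `"signal"` until the user relabels),
#'   `explained_variance` (non-increasing), `d`, `converged`, `grid` (if
#'   available), `mixing` (total-timepoints x d, if available).
#' @export
fastica_spatial <- function(reduction, tol = 1e-6, max_iter = 500, seed = 1) {
  if (inherits(reduction, "ica_reduction")) {
    Z <- reduction$whitened
    basis <- reduction$basis
    dewhiten <- reduction$dewhiten
    grid <- reduction$grid
  } else {
    Z <- as.matrix(reduction)
    basis <- NULL; dewhiten <- NULL; grid <- NULL
  }
  d <- nrow(Z); v <- ncol(Z)
  W <- with_local_seed(seed, matrix(stats::rnorm(d * d), d, d))
  W <- sym_decorrelate(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    gprime <- rowMeans(1 - G^2)
    W_new <- sym_decorrelate(tcrossprod(G, Z) / v - diag(gprime, d) %*% W)
    delta <- max(abs(1 - abs(rowSums(W_new * W))))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("fixed-point ICA did not converge in %d iterations (delta %.2e)",
                    max_iter, delta))
  S <- W %*% Z                               # d x v, unit-variance rows
  # sign convention: nonnegative skewness
  sk <- rowMeans(S^3)
  flip <- ifelse(sk < 0, -1, 1)
  S <- S * flip
  W <- W * flip
  # explained variance of the concatenated data per component
  if (!is.null(basis)) {
    A <- basis %*% dewhiten %*% t(W)         # total_t x d mixing
    ev <- colSums(A^2) * (v - 1) / v         # * ||S_i||^2 / v scaling constant
  } else {
    ev <- rep(1, d)
  }
  ord <- order(ev, decreasing = TRUE)        # stable for ties (radix)
  structure(list(maps = t(S[ord, , drop = FALSE]),
                 labels = rep("signal", d),
                 explained_variance = ev[ord],
                 d = d, converged = converged, grid = grid,
                 mixing = if (!is.null(basis)) (basis %*% dewhiten %*% t(W))[, ord, drop = FALSE]),
            class = "component_maps")
}

#' Temporal-concatenation group ICA
#'
#' Convenience wrapper: [concatenate_and_reduce()] followed by
#' [fastica_spatial()].
#'
#' @inheritParams concatenate_and_reduce
#' @inheritParams fastica_spatial
#' @param labels optional character vector of per-component labels
#'   (`"signal"`/`"artifact"`), applied after variance ranking.
#' @return A `component_maps` object (see [fastica_spatial()]).
#' @export
group_ica <- function(datasets, d, tol = 1e-6, max_iter = 500, seed = 1,
                      labels = NULL) {
  red <- concatenate_and_reduce(datasets, d)
  cm <- fastica_spatial(red, tol = tol, max_iter = max_iter, seed = seed)
  if (!is.null(labels)) cm <- set_component_labels(cm, labels)
  cm
}

#' Label components as signal or artifact
#'
#' Replaces the visual artifact classification of a human analyst: labels are
#' supplied explicitly (or taken from simulation truth in synthetic studies).
#'
#' @param component_maps a `component_maps` object.
#' @param labels character vector of length `d`, values `"signal"` or
#'   `"artifact"`.
#' @return The relabelled `component_maps`.
#' @export
set_component_labels <- function(component_maps, labels) {
  stopifnot(inherits(component_maps, "component_maps"))
  labels <- as.character(labels)
  if (length(labels) != component_maps$d ||
      !all(labels %in% c("signal", "artifact")))
    stop("`labels` must give 'signal' or 'artifact' for each component",
         call. = FALSE)
  component_maps$labels <- labels
  component_maps
}

#' @export
print.component_maps <- function(x, ...) {
  cat(sprintf("<component_maps> %d components x %d voxels (%d signal, %d artifact)%s\n",
              x$d, nrow(x$maps), sum(x$labels == "signal"),
              sum(x$labels == "artifact"),
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Match estimated component maps to reference maps
#'
#' Greedy matching on absolute spatial correlation; used to assess source
#' recovery in simulations.
#'
#' @param estimated voxels x d matrix (or `component_maps`).
#' @param reference voxels x d matrix of ground-truth maps.
#' @return tibble with `reference` (column index), `estimated` (matched column),
#'   `r` (signed spatial correlation of the match).
#' @export
match_components <- function(estimated, reference) {
  if (inherits(estimated, "component_maps")) estimated <- estimated$maps
  R <- stats::cor(reference, estimated)
  k <- ncol(reference)
  A <- abs(R)
  out <- vector("list", k)
  for (step in seq_len(k)) {
    idx <- arrayInd(which.max(A), dim(A))
    out[[step]] <- tibble::tibble(reference = idx[1], estimated = idx[2],
                                  r = R[idx[1], idx[2]])
    A[idx[1], ] <- -Inf
    A[, idx[2]] <- -Inf
  }
  res <- do.call(rbind, out)
  res[order(res$reference), ]
}
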