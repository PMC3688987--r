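# demean columns and scale each to unit sample variance (sd denominator n-1);
# zero-variance columns trigger an error naming the offender
normalize_columns <- function(x, what = "column") {
  x <- sweep(x, 2L, colMeans(x))
  sds <- sqrt(colSums(x^2) / (nrow(x) - 1))
  if (any(sds == 0))
    stop(sprintf("%s %s has zero variance", what,
                 paste(which(sds == 0), collapse = ", ")), call. = FALSE)
  sweep(x, 2L, sds, "/")
}

# error naming collinear columns of a rank-deficient design
check_full_rank <- function(X, what = "component") {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- sort(qrX$pivot[seq(qrX$rank + 1L, ncol(X))])
    stop(sprintf("design is rank deficient: %s(s) %s collinear with the others",
                 what, paste(bad, collapse = ", ")), call. = FALSE)
  }
  qrX
}

#' Dual regression, stage 1: subject network timeseries
#'
#' Each group component map is demeaned and normalized to unit variance over
#' voxels; all `d` maps (signal and artifact alike) enter one multiple
#' regression against every volume of the subject's data, solved by the
#' pseudo-inverse of the map matrix. The result is the subject's raw (not yet
#' normalized) network timeseries, whose column standard deviations are the
#' network amplitudes.
#'
#' @param dataset a [masked_dataset()].
#' @param group_maps a `component_maps` object or a voxels x d matrix.
#' @return `t x d` matrix of raw timeseries.
#' @export
stage1_timeseries <- function(dataset, group_maps) {
  stopifnot(inherits(dataset, "masked_dataset"))
  M <- if (inherits(group_maps, "component_maps")) group_maps$maps else as.matrix(group_maps)
  if (nrow(M) != ncol(dataset$data))
    stop("map voxel count does not match the dataset", call. = FALSE)
  M <- normalize_columns(M, "component map")
  qrM <- check_full_rank(M, "component")
  t(qr.coef(qrM, t(dataset$data)))
}

#' Dual regression, stage 2: subject spatial maps
#'
#' The stage-1 timeseries are demeaned and variance-normalized, then regressed
#' per voxel against the subject's data. Returns the beta maps and the
#' standard deviation of the per-voxel residual (denominator `t`), i.e. the
#' background-noise sd used for the z-transformation.
#'
#' @param dataset a [masked_dataset()].
#' @param timeseries_raw `t x d` stage-1 timeseries.
#' @return list with `beta_maps` (d x voxels) and `residual_sd` (voxels).
#' @export
stage2_maps <- function(dataset, timeseries_raw) {
  stopifnot(inherits(dataset, "masked_dataset"))
  Tn <- as.matrix(timeseries_raw)
  if (nrow(Tn) != nrow(dataset$data))
    stop("timeseries length does not match the dataset", call. = FALSE)
  Tn <- normalize_columns(Tn, "timeseries")
  qrT <- check_full_rank(Tn, "timeseries")
  beta <- qr.coef(qrT, dataset$data)              # d x voxels
  resid <- dataset$data - Tn %*% beta
  resid <- sweep(resid, 2L, colMeans(resid))       # sd of the residual
  residual_sd <- sqrt(colSums(resid^2) / nrow(resid))
  list(beta_maps = beta, residual_sd = residual_sd)
}

#' Z-transform subject spatial maps
#'
#' Divides each component weight by the standard deviation of the background
#' noise (the stage-2 residual sd at that voxel). Voxels with zero residual sd
#' map to 0; their count is attached as attribute `n_degenerate` and reported
#' via a warning.
#'
#' @param beta_maps d x voxels matrix.
#' @param residual_sd voxels vector.
#' @return d x voxels z-map matrix.
#' @export
z_transform_maps <- function(beta_maps, residual_sd) {
  beta_maps <- as.matrix(beta_maps)
  if (length(residual_sd) != ncol(beta_maps))
    stop("residual_sd length does not match the maps", call. = FALSE)
  zero <- residual_sd == 0
  denom <- ifelse(zero, 1, residual_sd)
  z <- sweep(beta_maps, 2L, denom, "/")
  z[, zero] <- 0
  if (any(zero))
    warning(sprintf("%d voxel(s) with zero residual sd mapped to z = 0", sum(zero)))
  attr(z, "n_degenerate") <- sum(zero)
  z
}

#' Full dual regression for one subject
#'
#' @inheritParams stage1_timeseries
#' @return An object of class `subject_decomposition`: `timeseries_raw`
#'   (t x d), `amplitudes` (column sds of the raw timeseries, sample
#'   convention), `beta_maps` (d x voxels), `residual_sd` (voxels), `z_maps`
#'   (d x voxels), `subject_id`.
#' @export
dual_regression <- function(dataset, group_maps) {
  ts_raw <- stage1_timeseries(dataset, group_maps)
  s2 <- stage2_maps(dataset, ts_raw)
  z <- suppressWarnings(z_transform_maps(s2$beta_maps, s2$residual_sd))
  structure(list(timeseries_raw = ts_raw,
                 amplitudes = apply(ts_raw, 2L, stats::sd),
                 beta_maps = s2$beta_maps,
                 residual_sd = s2$residual_sd,
                 z_maps = z,
                 n_degenerate = attr(z, "n_degenerate"),
                 subject_id = dataset$subject_id),
            class = "subject_decomposition")
}

#' @export
print.subject_decomposition <- function(x, ...) {
  cat(sprintf("<subject_decomposition> '%s': %d timepoints x %d components, %d voxels\n",
              x$subject_id, nrow(x$timeseries_raw), ncol(x$timeseries_raw),
              ncol(x$beta_maps)))
  cat("  amplitudes:", paste(sprintf("%.3f", x$amplitudes), collapse = ", "), "\n")
  invisible(x)
}
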